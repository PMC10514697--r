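source	statistic	count
IndexFungorum	TotalNames	507279
IndexFungorum	NamesWithPublications	444235
IndexFungorum	DOI	75009
IndexFungorum	Handle	3
IndexFungorum	JSTOR	5578
IndexFungorum	BioStor	322
IndexFungorum	BHL	6818
IndexFungorum	URL	32064
IndexFungorum	PDF	12864
IndexFungorum	WikidataQID	94192
IndexFungorum	Any	105886
IPNI	TotalNames	1721566
IPNI	NamesWithPublications	1708187
IPNI	DOI	245846
IPNI	Handle	1157
IPNI	JSTOR	131401
IPNI	BioStor	52395
IPNI	BHL	107459
IPNI	URL	97396
IPNI	PDF	34319
IPNI	WikidataQID	396072
IPNI	Any	522601
ION	TotalNames	5309468
ION	NamesWithPublications	1729338
ION	DOI	401351
ION	Handle	35731
ION	JSTOR	28146
ION	BioStor	170250
ION	BHL	5
ION	URL	127041
ION	PDF	231156
ION	WikidataQID	515341
ION	Any	769956
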