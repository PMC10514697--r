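lsid	name	rank	citation_string	source
urn:lsid:indexfungorum.org:names:839249	Cordyceps changchunensis	species	Hu, Dai, Zhao, Guo, Tuo, Rao, Qi, Zhang, Li & Zhang, IMA Fungus 83: 166 (2021)	IndexFungorum
urn:lsid:indexfungorum.org:names:840943	Neodeightonia mucosa	species	Frontiers in Microbiology, volume 12, issue no. 737541	IndexFungorum
urn:lsid:indexfungorum.org:names:356289	Phanerochaete exilis	species	Ginns, Mycotaxon 45: 120 (1992)	IndexFungorum
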