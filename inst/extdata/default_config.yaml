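# taxolink run configuration (all keys optional; defaults shown)
precedence: [DOI, Handle, JSTOR, BioStor, BHL, URL, PDF]
aliases:
  "Front. Microbiol.": "Frontiers in Microbiology"
  "IMA Fungus": "IMA Fungus"
  "MycoKeys": "MycoKeys"
  "Mycotaxon": "Mycotaxon"
equivalence_rules:
  - [indexfungorum.org, mycobank.org]
full_citation_threshold: 0.8
similarity_weights:
  container: 0.4
  volume: 0.2
  year: 0.2
  authors: 0.2
year_window: 1
continuous_k: 5
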