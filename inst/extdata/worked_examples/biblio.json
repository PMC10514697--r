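[
  {
    "id": "mycokeys-83-161",
    "container-title": "MycoKeys",
    "volume": "83",
    "page": "161-180",
    "issued": 2021,
    "title": "Hidden diversity of wood-inhabiting fungi",
    "author": [{"family": "Hu"}, {"family": "Dai"}, {"family": "Zhao"}, {"family": "Zhang"}],
    "DOI": "10.3897/mycokeys.83.72325",
    "QID": "Q105740570"
  },
  {
    "id": "frontmicro-12-737541",
    "container-title": "Frontiers in Microbiology",
    "volume": "12",
    "issued": 2021,
    "title": "Endophytic fungi of a mangrove host",
    "author": [{"family": "Li"}, {"family": "Wang"}],
    "DOI": "10.3389/fmicb.2021.737541",
    "article-number": "737541"
  },
  {
    "id": "mycotaxon-45-113",
    "container-title": "Mycotaxon",
    "volume": "45",
    "page": "113-129",
    "issued": 1992,
    "title": "New records of corticioid fungi",
    "author": [{"family": "Ginns"}],
    "URL": "https://example.org/mycotaxon/45/113"
  }
]
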