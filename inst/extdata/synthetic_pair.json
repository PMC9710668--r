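{
  "variants": [
    {
      "sequence": 1,
      "position": 20,
      "token": "p.S20C",
      "id": "rs000000001",
      "source": "synthetic example",
      "note": "human serine-to-cysteine substitution",
      "allele_frequency": "1.2e-5",
      "clinical_significance": "pathogenic"
    },
    {
      "sequence": 2,
      "position": 19,
      "token": "p.S19C",
      "source": "synthetic example",
      "note": "mouse counterpart of the human p.S20C variant"
    }
  ],
  "modifications": [
    {
      "sequence": 1,
      "position": 16,
      "type": "ubiquitination",
      "note": "K16-ub"
    }
  ],
  "regions": [
    {
      "sequence": 1,
      "start": 5,
      "end": 15,
      "label": "example domain",
      "url": "https://example.org/domain"
    }
  ]
}
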