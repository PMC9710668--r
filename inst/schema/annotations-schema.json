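{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "alnvista-annotations-1.0",
  "title": "Alignment annotation document",
  "description": "Variants, modifications and interval regions bound to the sequences of a FASTA alignment. Positions are 1-based ungapped sequence coordinates; 'sequence' is a 1-based record index or a record label. Global regions use alignment-column coordinates.",
  "type": "object",
  "properties": {
    "variants": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sequence", "position"],
        "properties": {
          "sequence": {"type": ["integer", "string"]},
          "position": {"type": "integer", "minimum": 1},
          "token": {"type": "string", "description": "HGVS-like substitution, e.g. p.C4957Y or c.88C>G"},
          "source": {"type": "string"},
          "note": {"type": "string", "description": "free text or HTML fragment for the pop-up"},
          "id": {"type": "string", "description": "variant identifier, e.g. rs121912606"},
          "url": {"type": "string"}
        },
        "additionalProperties": true
      }
    },
    "modifications": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["sequence", "position"],
        "properties": {
          "sequence": {"type": ["integer", "string"]},
          "position": {"type": "integer", "minimum": 1},
          "type": {"type": "string", "description": "e.g. ubiquitination"},
          "note": {"type": "string"},
          "url": {"type": "string"}
        },
        "additionalProperties": true
      }
    },
    "regions": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["start", "end"],
        "properties": {
          "sequence": {"type": ["integer", "string"], "description": "omit or use \"global\" for column-coordinate intervals"},
          "start": {"type": "integer", "minimum": 1},
          "end": {"type": "integer", "minimum": 1},
          "label": {"type": "string"},
          "color": {"type": "string"},
          "url": {"type": "string"}
        },
        "additionalProperties": true
      }
    }
  },
  "additionalProperties": false
}
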