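{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "citecheck citation instance (one JSON object per JSONL line)",
  "type": "object",
  "required": ["instance_id", "citing_doc_id", "reference_doc_id",
               "paragraph_text", "marker_span", "marker_multiplicity",
               "context_sentence_ids", "evidence_segments", "fine_label"],
  "properties": {
    "instance_id": {"type": "string"},
    "citing_doc_id": {"type": "string"},
    "reference_doc_id": {"type": "string"},
    "paragraph_text": {"type": "string"},
    "marker_span": {
      "description": "0-based half-open character interval of the target citation marker",
      "type": "array", "items": {"type": "integer"}, "minItems": 2, "maxItems": 2
    },
    "marker_multiplicity": {"enum": ["single", "multi"]},
    "other_marker_spans": {
      "type": "array",
      "items": {"type": "array", "items": {"type": "integer"}, "minItems": 2, "maxItems": 2}
    },
    "context_sentence_ids": {
      "description": "1-based paragraph-local sentence indices; always includes the citance",
      "type": "array", "items": {"type": "integer"}, "minItems": 1
    },
    "evidence_segments": {
      "description": "empty exactly when fine_label is IRRELEVANT or ETIQUETTE; at most 5 entries",
      "type": "array", "maxItems": 5,
      "items": {
        "type": "object",
        "required": ["reference_doc_id", "granularity", "unit_id"],
        "properties": {
          "reference_doc_id": {"type": "string"},
          "granularity": {"enum": ["sentence", "paragraph", "section"]},
          "unit_id": {"type": "string"}
        }
      }
    },
    "fine_label": {"enum": ["ACCURATE", "CONTRADICT", "NOT_SUBSTANTIATE",
                             "IRRELEVANT", "OVERSIMPLIFY", "MISQUOTE",
                             "INDIRECT", "ETIQUETTE"]},
    "coarse_label": {
      "description": "informative only; re-derived from fine_label on read",
      "enum": ["ACCURATE", "NOT_ACCURATE", "IRRELEVANT"]
    }
  }
}
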