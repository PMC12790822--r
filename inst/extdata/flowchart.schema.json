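{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "$id": "mirflow:flowchart",
  "title": "Curation flowchart",
  "description": "A typed DAG of filter/decision/terminal nodes executed by mirflow. Structural invariants beyond this schema (reachability, acyclicity, branch coverage, payload term membership of term_hierarchy) are enforced by validate_flowchart().",
  "type": "object",
  "required": ["name", "version", "root", "nodes"],
  "properties": {
    "name": {"type": "string"},
    "version": {"type": "string"},
    "root": {"type": "string", "description": "node_id of the entry node"},
    "term_hierarchy": {
      "type": "object",
      "description": "child GO id -> parent GO id (is_a)",
      "additionalProperties": {"type": "string", "pattern": "^GO:[0-9]{7}$"}
    },
    "nodes": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "required": ["kind"],
        "properties": {
          "kind": {"enum": ["filter", "decision", "terminal"]},
          "question": {"type": "string"},
          "section_hint": {
            "enum": ["abstract", "introduction", "methods", "results", "discussion"]
          },
          "yes_next": {"type": "string"},
          "no_next": {"type": "string"},
          "on_fail": {"enum": ["filtered", "no_annotation"]},
          "payload": {
            "type": "array",
            "minItems": 1,
            "items": {
              "type": "object",
              "required": ["term", "aspect"],
              "properties": {
                "term": {"type": "string", "pattern": "^GO:[0-9]{7}$"},
                "aspect": {"enum": ["BP", "MF"]}
              }
            }
          }
        }
      }
    }
  }
}
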