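[
  {"scope": "binding_filter",
   "pattern": "(?i)(luciferase|immunoprecipitation|pull-down|reporter assay|CRISPR)",
   "answer": "yes"},
  {"scope": "cluster_filter",
   "pattern": "(?i)(miRNA cluster|polycistronic)",
   "answer": "yes"},
  {"scope": "reporter_assay",
   "pattern": "(?i)luciferase reporter",
   "answer": "yes"},
  {"scope": "mrna_level",
   "pattern": "(?i)mRNA levels? decreased",
   "answer": "yes"},
  {"scope": "protein_level",
   "pattern": "(?i)protein levels? were markedly reduced[\\s\\S]*mRNA levels? remained unchanged",
   "answer": "yes"},
  {"scope": "heading:introduction", "pattern": "(?i)(introduction|background)"},
  {"scope": "heading:methods", "pattern": "(?i)(method|procedure|experimental)"},
  {"scope": "heading:results", "pattern": "(?i)(result|finding)"},
  {"scope": "heading:discussion", "pattern": "(?i)(discussion|concluding)"},
  {"scope": "target:*", "pattern": "(?i)luciferase[^.]*\\b{option}\\b"}
]
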