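# Functional-category keyword table for gene products.
# Categories are tried top to bottom; the first case-insensitive regex
# match wins. Edit freely and pass the file to feature_categories().
invertase:
  - "invertase"
recombinase:
  - "recombinase"
integrase:
  - "integrase"
transposase:
  - "transposase"
  - "insertion sequence"
  - "\\bIS[0-9]+\\b"
sus_tonB:
  - "TonB"
  - "SusC"
  - "SusD"
  - "RagA"
  - "RagB"
  - "\\bSus\\b"
  - "starch utilization"
capsule_lps:
  - "capsul[ae]"
  - "capsule biosynthesis"
  - "lipopolysaccharide"
  - "\\bLPS\\b"
  - "polysaccharide biosynthesis"
  - "polysaccharide export"
  - "glycosyltransferase"
  - "O-antigen"
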