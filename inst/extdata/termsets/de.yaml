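# Reconstructed German-style term lists for the radiology-report exclusion
# rule. Placeholder lists: review against local report language before use.
language_tag: de
negation_terms:
  - kein
  - keine
  - keinen
  - keinem
  - keiner
  - nicht
  - ohne
infiltrate_terms:
  - infiltrat
  - infiltrate
  - infiltraten
  - infiltrats
  - verschattung
  - pneumonie
restricting_terms:
  - aber
  - jedoch
  - allerdings
  - links
  - rechts
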