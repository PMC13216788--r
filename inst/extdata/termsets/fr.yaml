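# Reconstructed French-style term lists for the radiology-report exclusion
# rule. Placeholder lists: review against local report language before use.
language_tag: fr
negation_terms:
  - pas
  - sans
  - aucun
  - aucune
  - non
infiltrate_terms:
  - infiltrat
  - infiltrats
  - foyer
  - foyers
  - condensation
restricting_terms:
  - mais
  - cependant
  - toutefois
  - gauche
  - droit
  - droite
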