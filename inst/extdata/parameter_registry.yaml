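# Canonical 18-parameter registry for multiparametric mutation scoring.
#
# Four general categories: protein stability effects (predicted ddG),
# mutation position (secondary structure / interfaces / active site),
# evolutionary conservation (ConSurf grade of the mutated residue), and
# change in amino-acid properties. One additional evolutionary indicator
# (conserved substitution, the only negatively signed parameter) and one
# translational indicator (codon/tRNA availability) complete the list.
#
# ddG bands (kcal/mol): very destabilizing < -5.0; destabilizing
# [-5.0, -1.5); unchanged [-1.5, 1.5]; stabilizing (1.5, 5.0];
# very stabilizing > 5.0. The destabilizing-side edges are the published
# ones; the stabilizing side mirrors them.

thresholds:
  ddg_very_destabilizing: -5.0
  ddg_destabilizing: -1.5
  ddg_stabilizing: 1.5
  ddg_very_stabilizing: 5.0
  blosum_conserved_min: 1      # BLOSUM62 score > 0 counts as conserved
  rare_codon_max_per_thousand: 8.0

parameters:
  - name: ddg_very_destabilizing
    category: stability
    sign: 1
    condition: ddg_class
    value: very_destabilizing
  - name: ddg_destabilizing
    category: stability
    sign: 1
    condition: ddg_class
    value: destabilizing
  - name: ddg_stabilizing
    category: stability
    sign: 1
    condition: ddg_class
    value: stabilizing
  - name: ddg_very_stabilizing
    category: stability
    sign: 1
    condition: ddg_class
    value: very_stabilizing
  - name: in_helix
    category: position
    sign: 1
    condition: residue_flag
    field: helix
  - name: in_sheet
    category: position
    sign: 1
    condition: residue_flag
    field: sheet
  - name: in_dimer_interface
    category: position
    sign: 1
    condition: residue_flag
    field: dimer_interface
  - name: in_active_site
    category: position
    sign: 1
    condition: residue_flag
    field: active_site
  - name: consurf_max
    category: conservation
    sign: 1
    condition: consurf_grade
    grades: [9]
  - name: consurf_high
    category: conservation
    sign: 1
    condition: consurf_grade
    grades: [8]
  - name: consurf_moderate
    category: conservation
    sign: 1
    condition: consurf_grade
    grades: [7]
  - name: proline_change
    category: property
    sign: 1
    condition: property
    property: proline
  - name: glycine_change
    category: property
    sign: 1
    condition: property
    property: glycine
  - name: size_change
    category: property
    sign: 1
    condition: property
    property: size
  - name: polarity_change
    category: property
    sign: 1
    condition: property
    property: polarity
  - name: charge_change
    category: property
    sign: 1
    condition: property
    property: charge
  - name: conserved_substitution
    category: evolution
    sign: -1
    condition: conserved_substitution
  - name: rare_codon
    category: translation
    sign: 1
    condition: rare_codon
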