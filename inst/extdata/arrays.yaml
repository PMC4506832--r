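# Example electrode-array geometry registry (see ?array_registry).
# Spacings are arc distances in mm from electrode 1 (most apical contact);
# uniform placeholder layouts consistent with the per-array insertion-angle
# distributions. Replace span_mm or spacings_mm with manufacturer data if
# available.
PMA:
  n_contacts: 22
  span_mm: 14.0
SA:
  n_contacts: 22
  span_mm: 15.0
SSA:
  n_contacts: 22
  span_mm: 16.0
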