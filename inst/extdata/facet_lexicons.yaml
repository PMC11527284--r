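# Example facet lexicons (synthetic surfaces). Replace the maps with the
# surface forms of your corpus; matching is lower-cased and
# whitespace-collapsed.
sex:
  male: male
  man: male
  female: female
  woman: female
edu:
  master: master
  masters: master
  msc: master
  phd: doctor
  doctoral: doctor
  doctorate: doctor
world_class:
  - ORG1_a ORG1_b
  - ORG2_a ORG2_b ORG2_c
  - ORG3_a
  - ORG4_a ORG4_b
  - ORG5_a ORG5_b ORG5_c
  - ORG6_a
  - ORG7_a ORG7_b
  - ORG8_a ORG8_b ORG8_c
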