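# Example rs6265 genotype count tables (AA, AG, GG) by POCD status,
# from a published case-control study of BDNF rs6265 and POCD in
# elderly surgical patients. Used by `associate --counts` and the
# package examples; note the month3 block's genotype counts sum to
# 25 / 74 subjects although the study's stated 3-month group sizes
# were 18 / 81 — check_genotype_table() flags this.
day7:
  pocd: [10, 16, 3]
  no_pocd: [11, 39, 20]
month3:
  pocd: [8, 12, 5]
  no_pocd: [13, 43, 18]
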