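# Four vitamin D pathway SNPs: designated major/minor (risk) alleles and
# non-Finnish European reference minor-allele frequencies.
- snp_id: rs12785878
  gene: DHCR7
  major: T
  minor: G
  ref_maf: 0.278
- snp_id: rs2282679
  gene: GC
  major: T
  minor: G
  ref_maf: 0.288
- snp_id: rs2060793
  gene: CYP2R1
  major: G
  minor: A
  ref_maf: 0.403
- snp_id: rs6013897
  gene: CYP24A1
  major: T
  minor: A
  ref_maf: 0.197
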