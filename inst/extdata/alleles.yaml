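# Fixture ABO allele-definition table.
#
# Coding contents follow ISBT convention relative to the ABO*A1.01 mapping
# reference; subtype alleles are expressed as deltas on a parent allele.
# The c.29-1053_29-1037del intron-1 deletion is carried as a shared
# O-lineage haplotype variant (present on both O.01.01 and O.01.02
# backgrounds), so it is not allele-specific. Replace this file to use the
# full ISBT catalog.
reference: "ABO*A1.01"
alleles:
  - name: "ABO*A1.01"
  - name: "ABO*A1.02"
    coding: ["c.467C>T"]
  - name: "ABO*B.01"
    coding: ["c.297A>G", "c.526C>G", "c.657C>T", "c.703G>A", "c.796C>A",
             "c.803G>C", "c.930G>A"]
  - name: "ABO*O.01.01"
    coding: ["c.261delG"]
    intronic: ["c.29-1053_29-1037del"]
  - name: "ABO*O.01.02"
    coding: ["c.106G>T", "c.188G>A", "c.189C>T", "c.220C>T", "c.261delG",
             "c.297A>G", "c.646T>A", "c.681G>A", "c.771C>T", "c.829G>A"]
    intronic: ["c.29-1053_29-1037del"]
  - name: "ABO*B3.10"
    parent: "ABO*B.01"
    coding: ["c.28G>A"]
    subtype: true
  - name: "ABO*AW.37"
    parent: "ABO*A1.02"
    coding: ["c.940A>G"]
    subtype: true
  - name: "ABO*BW.03"
    parent: "ABO*B.01"
    coding: ["c.721C>T"]
    subtype: true
  - name: "ABO*BW.28"
    parent: "ABO*B.01"
    coding: ["c.541T>C"]
    subtype: true
  - name: "ABO*A2.07"
    parent: "ABO*A1.01"
    coding: ["c.539G>C"]
    subtype: true
  - name: "ABO*A2.08"
    parent: "ABO*A1.02"
    coding: ["c.539G>C"]
    subtype: true
  - name: "ABO*BA.02"
    parent: "ABO*B.01"
    coding: ["c.700C>G"]
    subtype: true
  - name: "ABO*BA.07"
    parent: "ABO*B.01"
    coding: ["c.701C>T"]
    subtype: true
  - name: "ABO*cisAB.01"
    parent: "ABO*A1.02"
    coding: ["c.803G>C"]
    subtype: true
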