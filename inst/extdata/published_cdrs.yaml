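# Registry metadata for the eleven published FN clinical decision rules
# validated by this package. The tier functions live in R code
# (published_cdrs()); this document records, per rule, the default mapping
# of the publication's target outcome onto the episode schema and the
# schema-representable part of the original eligibility criteria applied to
# build the restricted validation dataset (rVD).
rules:
  - id: rackoff
    label: "Rackoff 1996"
    tiers: [low, intermediate, high]
    target_outcome: bacteremia
    rvd_filter: "exclude inpatient-onset FN"
  - id: klaassen
    label: "Klaassen 2000"
    tiers: [low, high]
    target_outcome: sre
    rvd_filter: "exclude newly diagnosed, prior HSCT, inpatient onset"
  - id: baorto
    label: "Baorto 2001"
    tiers: [low, high]
    target_outcome: bacteremia
    rvd_filter: "exclude age < 1 y, prior HSCT"
  - id: madsen
    label: "Madsen 2002"
    tiers: [low, high]
    target_outcome: bacteremia
    rvd_filter: "exclude prior HSCT, inpatient onset"
  - id: rondinelli
    label: "Rondinelli 2006"
    tiers: [low, intermediate, high]
    target_outcome: sre
    rvd_filter: "exclude prior HSCT, inpatient onset, non-first FN episodes"
  - id: spog_ae
    label: "SPOG-AE (Ammann) 2010"
    tiers: [low, high]
    target_outcome: sre
    rvd_filter: "exclude inpatient-onset FN"
  - id: hakim
    label: "Hakim 2010"
    tiers: [low, high]
    target_outcome: sre
    rvd_filter: "exclude prior HSCT, inpatient onset"
  - id: suttitossatam
    label: "Suttitossatam 2020"
    tiers: [low, high]
    target_outcome: smc
    rvd_filter: "exclude age < 1 y"
  - id: aus_lbi
    label: "AUS (Haeusler) 2020, likely bacterial infection"
    tiers: [low, high]
    target_outcome: sre
    rvd_filter: "exclude recent HSCT"
  - id: aus_bacteremia
    label: "AUS (Haeusler) 2020, bacteremia"
    tiers: [low, high]
    target_outcome: bacteremia
    rvd_filter: "exclude recent HSCT"
  - id: aus_icu
    label: "AUS (Haeusler) 2020, ICU admission"
    tiers: [low, high]
    target_outcome: smc
    rvd_filter: "exclude recent HSCT"
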