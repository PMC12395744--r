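# Synthetic placeholder screening threshold table. Structure mirrors a
# risk-based trial policy: age bands partition 40-74, risk intervals are
# half-open lower-inclusive and partition (0, 1), and an extreme-density
# override escalates to at least annual screening. The values are invented;
# a real threshold table in the same format can be dropped in verbatim.
age_bands:
  - ages: [40, 49]
    rules:
      - {risk_lo: 0.0,    risk_hi: 0.012,  recommendation: none_or_stop}
      - {risk_lo: 0.012,  risk_hi: 0.0167, recommendation: biennial}
      - {risk_lo: 0.0167, risk_hi: 0.04,   recommendation: annual_risk}
      - {risk_lo: 0.04,   risk_hi: 1.0,    recommendation: q6mo_alternating}
  - ages: [50, 74]
    rules:
      - {risk_lo: 0.0,    risk_hi: 0.004,  recommendation: none_or_stop}
      - {risk_lo: 0.004,  risk_hi: 0.04,   recommendation: biennial}
      - {risk_lo: 0.04,   risk_hi: 0.08,   recommendation: annual_risk}
      - {risk_lo: 0.08,   risk_hi: 1.0,    recommendation: q6mo_alternating}
density_overrides:
  - {density: d, recommendation: annual_density}
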