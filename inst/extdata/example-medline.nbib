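PMID- 10000001
TI  - Metformin versus placebo for glycaemic control in adults with type 2
      diabetes: a randomised controlled trial
AB  - Background: Glycaemic control remains the cornerstone of type 2
      diabetes management. Methods: We randomised 420 adults to metformin or
      placebo for 24 weeks. Results: HbA1c fell by 1.1% in the metformin
      arm versus 0.2% with placebo. Conclusions: Metformin improved
      glycaemic control with acceptable tolerability.

PMID- 10000002
TI  - Prevalence of vitamin D deficiency in community-dwelling older adults
AB  - A cross-sectional survey of serum 25-hydroxyvitamin D concentrations
      in 900 community-dwelling adults aged over 65 years.

PMID- 10000003
TI  - Protocol for a cohort study of dietary patterns and incident stroke
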