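TY  - JOUR
AN  - 20000001
TI  - Intensive blood pressure lowering after ischaemic stroke: a randomised trial
AB  - We compared intensive with guideline blood pressure targets in 1200
  patients with recent ischaemic stroke and followed recurrent vascular
  events over two years.
ER  -
TY  - JOUR
AN  - 20000002
T1  - Screening instruments for atrial fibrillation in primary care
N2  - A diagnostic accuracy review of single-lead ECG devices against
  12-lead ECG reference standards.
ER  -
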