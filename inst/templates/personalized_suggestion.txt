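You are given the knowledge relevant to prescribing for a patient with a known
diagnosis and genotype. For each medication mentioned, state what the facts
imply for this patient: effective, ineffective, altered efficacy, or altered
risk of specific side effects, and under which genotype each implication holds.

Facts:
{{facts}}

{{constraint}}
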