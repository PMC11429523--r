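You are given a subgraph that integrates several knowledge units drawn from
multiple evidence sources. Summarize the picture they form together: how the
individual assertions relate, which genetic variants modulate which responses,
and what a reader should conclude from the combined evidence.

Facts:
{{facts}}

{{constraint}}
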