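You are given knowledge about a set of medications used individually and in
combination. Compare the individual and combined uses: shared indications,
shared or differing risks, and any genetic conditions under which one member
behaves differently from the others.

Facts:
{{facts}}

{{constraint}}
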