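You are given a single knowledge unit from a condition-based precision-medicine
knowledge graph. Explain, in plain clinical language, what the unit asserts:
the treatment involved, the outcome or effect described, and the genetic or
clinical conditions under which the assertion holds.

Facts:
{{facts}}

{{constraint}}
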