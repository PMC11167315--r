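# NLM Scrubber output vocabulary; extracts no contact-information spans.

schema: sys-nlm-scrubber
dialect: brat

[Name]  # does not distinguish name categories
extract: NAME
tier0: PII
tier1: Names
tier2: unmapped

[Address]
extract: ADDRESS
tier0: PII
tier1: Address
tier2: unmapped

[ID]
extract: ID
tier0: PII
tier1: Identifiers
tier2: unmapped

[Age]
extract: AGE
tier0: PII
tier1: Age
tier2: Age

[Date]
extract: DATE
tier0: PII
tier1: Time
tier2: Date
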