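# Philter output vocabulary: one catch-all class plus dates.

schema: sys-philter
dialect: brat

[PHI]  # catch-all over every PII category except dates; tier-1 precision against Names is expected to be very low
extract: PHI
tier0: PII
tier1: Names
tier2: unmapped

[Date]
extract: DATE
tier0: PII
tier1: Time
tier2: Date
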