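# MIST output vocabulary (distinguishes name categories).

schema: sys-mist
dialect: brat

[Patient]
extract: PATIENT
tier0: PII
tier1: Names
tier2: Patient

[Provider]
extract: PROVIDER
tier0: PII
tier1: Names
tier2: Provider

[Address]  # one coarse address class; no tier-2 analogue
extract: ADDRESS
tier0: PII
tier1: Address
tier2: unmapped

[Hospital]
extract: HOSPITAL
tier0: PII
tier1: Address
tier2: Hospital

[Phone]
extract: PHONE
tier0: PII
tier1: ContactInformation
tier2: Phone

[Email]
extract: EMAIL
tier0: PII
tier1: ContactInformation
tier2: Email

[ID]
extract: ID
tier0: PII
tier1: Identifiers
tier2: OtherID

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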