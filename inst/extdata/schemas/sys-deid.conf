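# deid (PhysioNet) output vocabulary: a reduced category set.

schema: sys-deid
dialect: brat

[Patient]
extract: Patient
tier0: PII
tier1: Names
tier2: Patient

[Doctor]
extract: Doctor
tier0: PII
tier1: Names
tier2: Provider

[Location]
extract: Location
tier0: PII
tier1: Address
tier2: OtherGeo

[Hospital]
extract: Hospital
tier0: PII
tier1: Address
tier2: Hospital

[Phone]
extract: Phone
tier0: PII
tier1: ContactInformation
tier2: Phone

[Age]
extract: Age
tier0: PII
tier1: Age
tier2: Age

[Date]
extract: Date
tier0: PII
tier1: Time
tier2: Date

[ID]
extract: ID
tier0: PII
tier1: Identifiers
tier2: OtherID
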