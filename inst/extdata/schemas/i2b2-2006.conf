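# 2006 i2b2 shared task: 8 native categories.

schema: i2b2-2006
dialect: inline_xml

[Location]
extract: LOCATION
tier0: PII
tier1: Address
tier2: OtherGeo

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

[Doctor]
extract: DOCTOR
tier0: PII
tier1: Names
tier2: Provider

[Patient]
extract: PATIENT
tier0: PII
tier1: Names
tier2: Patient

[MedicalRecord]
extract: ID
tier0: PII
tier1: Identifiers
tier2: MedicalRecord

[Age]  # strict HIPAA: this corpus annotates only ages over 89
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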