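# CliniDeID output vocabulary (distinguishes name categories).

schema: sys-clinideid
dialect: brat

[PTName]
extract: PTName
tier0: PII
tier1: Names
tier2: Patient

[HCPName]
extract: HCPName
tier0: PII
tier1: Names
tier2: Provider

[Relative]  # attested in documentation, rarely emitted
extract: Relative
tier0: PII
tier1: Names
tier2: Relative

[OtherPerson]
extract: OtherPerson
tier0: PII
tier1: Names
tier2: OtherPerson

[Street]
extract: Street
tier0: PII
tier1: Address
tier2: Street

[City]
extract: City
tier0: PII
tier1: Address
tier2: City

[State]
extract: State
tier0: PII
tier1: Address
tier2: State

[Country]
extract: Country
tier0: PII
tier1: Address
tier2: Country

[Zip]
extract: Zip
tier0: PII
tier1: Address
tier2: Zip

[OtherGeo]
extract: OtherGeo
tier0: PII
tier1: Address
tier2: OtherGeo

[Phone]
extract: Phone
tier0: PII
tier1: ContactInformation
tier2: Phone

[Fax]
extract: Fax
tier0: PII
tier1: ContactInformation
tier2: Fax

[Email]
extract: Email
tier0: PII
tier1: ContactInformation
tier2: Email

[URL]
extract: URL
tier0: PII
tier1: ContactInformation
tier2: URL

[SSN]
extract: SSN
tier0: PII
tier1: Identifiers
tier2: SSN

[MedicalRecord]
extract: MedicalRecord
tier0: PII
tier1: Identifiers
tier2: MedicalRecord

[OtherID]
extract: OtherID
tier0: PII
tier1: Identifiers
tier2: OtherID

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

[Occupation]
extract: Occupation
tier0: PII
tier1: Occupations
tier2: Occupation
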