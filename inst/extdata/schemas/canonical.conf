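# The curated tier taxonomy itself: tier-2 categories as natives. Used by the synthetic generator.

schema: canonical
dialect: brat

[Patient]
extract: Patient
tier0: PII
tier1: Names
tier2: Patient

[Provider]
extract: Provider
tier0: PII
tier1: Names
tier2: Provider

[Relative]
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

[Hospital]
extract: Hospital
tier0: PII
tier1: Address
tier2: Hospital

[Organization]
extract: Organization
tier0: PII
tier1: Address
tier2: Organization

[OtherGeo]
extract: OtherGeo
tier0: PII
tier1: Address
tier2: OtherGeo

[Age]
extract: Age
tier0: PII
tier1: Age
tier2: Age

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

[IPAddress]
extract: IPAddress
tier0: PII
tier1: ContactInformation
tier2: IPAddress

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

[HealthPlan]
extract: HealthPlan
tier0: PII
tier1: Identifiers
tier2: HealthPlan

[Account]
extract: Account
tier0: PII
tier1: Identifiers
tier2: Account

[License]
extract: License
tier0: PII
tier1: Identifiers
tier2: License

[Vehicle]
extract: Vehicle
tier0: PII
tier1: Identifiers
tier2: Vehicle

[Device]
extract: Device
tier0: PII
tier1: Identifiers
tier2: Device

[BioID]
extract: BioID
tier0: PII
tier1: Identifiers
tier2: BioID

[OtherID]
extract: OtherID
tier0: PII
tier1: Identifiers
tier2: OtherID

[Occupation]
extract: Occupation
tier0: PII
tier1: Occupations
tier2: Occupation

[Date]
extract: Date
tier0: PII
tier1: Time
tier2: Date
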