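# NeuroNER output vocabulary: mirrors the 2014 schema it was trained on.

schema: sys-neuroner
dialect: brat

[Patient]
extract: PATIENT
tier0: PII
tier1: Names
tier2: Patient

[Doctor]
extract: DOCTOR
tier0: PII
tier1: Names
tier2: Provider

[Username]
extract: USERNAME
tier0: PII
tier1: Identifiers
tier2: OtherID

[Profession]
extract: PROFESSION
tier0: PII
tier1: Occupations
tier2: Occupation

[Room]
extract: ROOM
tier0: PII
tier1: Address
tier2: OtherGeo

[Department]
extract: DEPARTMENT
tier0: PII
tier1: Address
tier2: OtherGeo

[Hospital]
extract: HOSPITAL
tier0: PII
tier1: Address
tier2: Hospital

[Organization]
extract: ORGANIZATION
tier0: PII
tier1: Address
tier2: Organization

[Street]
extract: STREET
tier0: PII
tier1: Address
tier2: Street

[City]
extract: CITY
tier0: PII
tier1: Address
tier2: City

[State]
extract: STATE
tier0: PII
tier1: Address
tier2: State

[Country]
extract: COUNTRY
tier0: PII
tier1: Address
tier2: Country

[Zip]
extract: ZIP
tier0: PII
tier1: Address
tier2: Zip

[LocationOther]
extract: LOCATION-OTHER
tier0: PII
tier1: Address
tier2: OtherGeo

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

[Phone]  # phone and fax pair into one tier-1 scoring value in this schema
extract: PHONE
tier0: PII
tier1: PhoneFax
tier2: Phone

[Fax]
extract: FAX
tier0: PII
tier1: PhoneFax
tier2: Fax

[Email]
extract: EMAIL
tier0: PII
tier1: ContactInformation
tier2: Email

[URL]
extract: URL
tier0: PII
tier1: ContactInformation
tier2: URL

[IPAddress]
extract: IPADDRESS
tier0: PII
tier1: ContactInformation
tier2: IPAddress

[SSN]
extract: SSN
tier0: PII
tier1: Identifiers
tier2: SSN

[MedicalRecord]
extract: MEDICALRECORD
tier0: PII
tier1: Identifiers
tier2: MedicalRecord

[HealthPlan]
extract: HEALTHPLAN
tier0: PII
tier1: Identifiers
tier2: HealthPlan

[Account]
extract: ACCOUNT
tier0: PII
tier1: Identifiers
tier2: Account

[License]
extract: LICENSE
tier0: PII
tier1: Identifiers
tier2: License

[Vehicle]
extract: VEHICLE
tier0: PII
tier1: Identifiers
tier2: Vehicle

[Device]
extract: DEVICE
tier0: PII
tier1: Identifiers
tier2: Device

[BioID]
extract: BIOID
tier0: PII
tier1: Identifiers
tier2: BioID

[IDNum]
extract: IDNUM
tier0: PII
tier1: Identifiers
tier2: OtherID
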