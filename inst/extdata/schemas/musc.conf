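# MUSC corpus schema.

schema: musc
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

[StreetCity]  # merged street+city spans from a guideline change
extract: StreetCity
tier0: PII
tier1: Address
tier2: StreetCity

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

[StateCountry]  # merged state+country spans
extract: StateCountry
tier0: PII
tier1: Address
tier2: StateCountry

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

[SSN]
extract: SSN
tier0: PII
tier1: Identifiers
tier2: SSN

[Other ID]  # every non-SSN identifier class
extract: Other_ID
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

[Occupation]
extract: Occupation
tier0: PII
tier1: Occupations
tier2: Occupation
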