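Dr. Maria Lopez saw John Smith, a 92-year-old retired welder, at Mercy Hospital on 3/15/2019. Call (555) 012-3456 with questions.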