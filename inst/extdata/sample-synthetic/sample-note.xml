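<?xml version="1.0" encoding="UTF-8"?>
<document doc_id="sample-note">
  <TEXT>Dr. Maria Lopez saw John Smith, a 92-year-old retired welder, at Mercy Hospital on 3/15/2019. Call (555) 012-3456 with questions.</TEXT>
  <TAGS>
    <TAG start="4" end="15" TYPE="Provider"/>
    <TAG start="20" end="30" TYPE="Patient"/>
    <TAG start="34" end="36" TYPE="Age"/>
    <TAG start="46" end="60" TYPE="Occupation"/>
    <TAG start="65" end="79" TYPE="Hospital"/>
    <TAG start="83" end="92" TYPE="Date"/>
    <TAG start="99" end="113" TYPE="Phone"/>
  </TAGS>
</document>
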