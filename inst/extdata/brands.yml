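# Brand-mention lexicon. The original analysis coded 32 brands but printed
# only the ones below (top mentions in either tweet class plus the brands
# named among the search keywords); the list is user-editable. Matching is
# casefolded on word boundaries.
blu:
  - blu
V2:
  - v2
  - v2 cigs
Green Smoke:
  - green smoke
Premium:
  - premium
Luci:
  - luci
Vapor4Life:
  - vapor4life
  - vapor 4 life
Volcano:
  - volcano
NicStick:
  - nicstick
eSmoke:
  - esmoke
NJOY:
  - njoy
South Beach Smoke:
  - south beach smoke
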