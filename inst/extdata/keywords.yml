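# Topical keyword syntax defining "tweets about e-cigarettes".
# The original search used 55 keywords; only the terms below were ever
# published (general terms, use terms, and the coded brand names). Edit
# freely; single tokens match on word boundaries, phrases as substrings.
include:
  - electronic cigarette
  - electronic cigarettes
  - e-cigarette
  - e-cigarettes
  - ecigarette
  - ecigarettes
  - ecig
  - ecigs
  - e-cig
  - e-cigs
  - e cig
  - eliquid
  - e-liquid
  - ejuice
  - vaping
  - vape
  - vapes
  - vaped
  - vaper
  - blu
  - njoy
  - green smoke
  - v2 cigs
  - vapor4life
  - nicstick
  - esmoke
  - south beach smoke
exclude:
  - marijuana
  - hookah
  - weed
  - shisha
  - blunt
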