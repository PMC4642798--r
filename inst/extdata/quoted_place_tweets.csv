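text,expected_category
"my teacher yells at me everyday for vaping in class...",class
"Vaping in the bathroom #whatofit",bathroom
"I do love being able to smoke in my room again doe! #ecig",house/room/in bed
"Is this guy really smoking an electronic cigarette in class? #Yes #wtf",class
"The guys in my office are smoking electronic cigarettes, its rather strange seeing smoke indoors, in an office, in the daytime",work
"My professor was just smoking his electronic cigarette in class, is that illegal?",class
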