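# Tweet cleaning rules applied before part-of-speech tagging.
# Only a handful of interjections, subordinate phrases and slang fixes were
# ever published for the original analysis; the lists below ship those items
# plus a small documented extension and are fully user-editable.
interjections:
  - lol
  - smh
  - lmao
  - lmfao
  - rofl
  - omg
  - omfg
  - haha
  - hahaha
  - ugh
  - duh
  - hmm
  - yo
  - damn
  - af
subordinate_phrases:
  - in the middle
  - at least
  - at all
# "in front of <X>" is removed only when X is not a person; when X is a
# person the phrase is a genuine place mention ("in front of someone").
in_front_person_words:
  - me
  - you
  - him
  - her
  - us
  - them
  - someone
  - everyone
  - everybody
  - people
  - mom
  - mum
  - dad
  - mother
  - father
  - parents
  - teacher
  - teachers
  - professor
  - kids
  - friends
  - girlfriend
  - boyfriend
  - family
  - class
slang_map:
  ur: "you're"
  u: "you"
  im: "i'm"
  tho: "though"
  cuz: "because"
  b4: "before"
  rn: "right now"
  ppl: "people"
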