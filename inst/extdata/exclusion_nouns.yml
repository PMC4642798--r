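# Nouns that commonly head prepositional phrases but do not name a physical
# location; phrases whose object head is one of these are discarded.
# The published examples are "night" and "life"; the rest are a documented
# extension covering times, abstractions and online "places".
non_location_nouns:
  - night
  - life
  - morning
  - everyday
  - today
  - yesterday
  - tomorrow
  - weekend
  - time
  - times
  - minute
  - minutes
  - hour
  - hours
  - day
  - days
  - week
  - weeks
  - month
  - months
  - year
  - years
  - moment
  - second
  - seconds
  - while
  - way
  - fact
  - love
  - peace
  - mood
  - hurry
  - row
  - bit
  - end
  - case
  - point
  - general
  - rate
  - phone
  - twitter
  - facebook
  - instagram
  - internet
  - tv
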