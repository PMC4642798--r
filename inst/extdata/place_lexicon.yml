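# Synonym lexicon mapping prepositional-phrase objects onto the 20 place
# categories. Multiword entries match consecutive tokens anywhere in the
# object and take priority over single-word head matches (so "locker room"
# is not swallowed by "room", nor "coffee shop" by "shop").
class:
  - class
  - classroom
house/room/in bed:
  - house
  - home
  - room
  - bedroom
  - bed
  - couch
  - basement
  - kitchen
school:
  - school
  - campus
public place:
  - public
bathroom:
  - bathroom
  - bathrooms
  - restroom
  - toilet
work:
  - work
  - office
  - job
  - workplace
  - desk
in front of someone:
  - front
car:
  - car
  - truck
  - van
  - backseat
restaurant:
  - restaurant
  - diner
movie theater:
  - movie theater
  - movie theatre
  - theater
  - theatre
  - movies
  - cinema
airplanes/airport:
  - plane
  - airplane
  - airport
  - flight
  - jet
store:
  - store
  - shop
bars/clubs:
  - bar
  - club
  - pub
dormitory:
  - dorm
  - dormitory
library:
  - library
mall:
  - mall
bowling alley:
  - bowling alley
  - alley
cafe/coffee shop:
  - coffee shop
  - cafe
  - coffeehouse
  - starbucks
hospital:
  - hospital
locker room:
  - locker room
  - locker
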