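# Compact open lexicon for linguistic reference metrics.
#
# Pronoun and tense-marker lists are closed-class and intended to be faithful;
# the positive/negative tone lists are a small curated approximation of a
# sentiment dictionary and are documented as heuristic. All entries lowercase;
# pronoun categories are pairwise disjoint. Apostrophes are plain ASCII (the
# tokenizer normalizes curly apostrophes).
first_person:
  - i
  - i'm
  - i've
  - i'll
  - i'd
  - me
  - my
  - mine
  - myself
  - we
  - we're
  - we've
  - we'll
  - we'd
  - us
  - our
  - ours
  - ourselves
second_person:
  - you
  - you're
  - you've
  - you'll
  - you'd
  - your
  - yours
  - yourself
  - yourselves
third_person:
  - she
  - she's
  - she'd
  - she'll
  - her
  - hers
  - herself
  - he
  - he's
  - he'd
  - he'll
  - him
  - his
  - himself
third_plural:
  - they
  - they're
  - they've
  - they'll
  - they'd
  - them
  - their
  - theirs
  - themselves
tense_present:
  - am
  - is
  - are
  - be
  - being
  - do
  - does
  - doing
  - have
  - has
  - can
  - it's
  - that's
  - there's
  - now
  - today
  - nowadays
tense_past:
  - was
  - were
  - been
  - did
  - had
  - used
  - went
  - got
  - said
  - made
  - felt
  - thought
  - yesterday
  - ago
  - before
tense_future:
  - will
  - won't
  - wouldn't
  - gonna
  - shall
  - tomorrow
  - soon
  - later
tone_positive:
  - good
  - great
  - happy
  - glad
  - love
  - loved
  - enjoy
  - enjoyed
  - fun
  - nice
  - wonderful
  - amazing
  - better
  - best
  - hope
  - hopeful
  - excited
  - awesome
  - pleasant
  - calm
  - relaxed
  - proud
  - grateful
tone_negative:
  - bad
  - sad
  - down
  - depressed
  - hopeless
  - tired
  - exhausted
  - terrible
  - awful
  - worse
  - worst
  - hate
  - hated
  - lonely
  - alone
  - worthless
  - guilty
  - anxious
  - worried
  - stressed
  - angry
  - upset
  - miserable
  - cry
  - cried
  - crying
  - fail
  - failure
  - empty
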