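# Illustrative keyword/blacklist configuration for the stream filter.
# NON-AUTHORITATIVE: production keyword lists used by surveillance platforms
# are curated continuously and are not public; this file only demonstrates
# the structure (tracked terms, ambiguous slang bound to usage terms, and a
# blacklist of common false positives).
unambiguous:
  - cannabis
  - marijuana
  - weed
  - dabs
  - edibles
  - synthetic cannabinoid
  - k2 spice
ambiguous:
  blunt:
    - smoke
    - smoked
    - smoking
    - roll
    - rolling
    - lit
  spice:
    - smoke
    - smoked
    - smoking
    - high
    - synthetic
  lean:
    - drink
    - drank
    - drinking
    - sip
    - sipping
  pot:
    - smoke
    - smoked
    - smoking
    - high
    - stoned
blacklist:
  - emily blunt
  - pumpkin spice latte
  - pumpkin spice
  - spice girls
  - pot roast
  - lean startup
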