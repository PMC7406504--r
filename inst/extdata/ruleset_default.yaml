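# Default habitat ruleset: ordered first-match rules over the synthetic
# legend set, anthropogenic classes first. Codes use the decade encoding
# (1.6 -> 106, 14.5 -> 1405). Layer names refer to the classification stack;
# `pasture`, `plantation`, `rural_gardens`, `montane`, `tropics` and
# `mangrove` are derived masks built by the mask-builder stage.
#
# Predicates are reconstructed from the published class definitions; rules
# marked "provisional" stand in where the full coded ruleset is not public.
# Supply your own ruleset file to parse_ruleset() to override any of this.
name: default
rules:
  # ---- artificial classes (always mapped first) ----
  - target: 1405            # Urban Areas
    group: artificial
    when: {atom: code_in, layer: land_cover, codes: [50]}
  - target: 1404            # Rural Gardens: very small arable fields near urban
    group: artificial
    when: {atom: mask, layer: rural_gardens}
  - target: 1401            # Arable Land
    group: artificial
    when: {atom: code_in, layer: land_cover, codes: [40]}
  - target: 1403            # Plantations (managed/planted forest classes)
    group: artificial
    when: {atom: mask, layer: plantation}
  - target: 1402            # Pastureland (LSU-thresholded, forest-suitable climate)
    group: artificial
    when: {atom: mask, layer: pasture}
  # ---- forest ----
  - target: 109             # tropical moist montane
    group: natural
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [10]}
        - {atom: mask, layer: tropics}
        - {atom: mask, layer: montane}
  - target: 107             # mangrove (expert mask); provisional
    group: natural
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [10]}
        - {atom: mask, layer: mangrove}
  - target: 108             # tropical swamp forest; provisional
    group: natural
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [10]}
        - {atom: code_in, layer: wetlands, codes: [4]}
  - target: 106             # tropical moist lowland
    group: natural
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [10]}
        - {atom: mask, layer: tropics}
  - target: 104             # temperate forest
    group: natural
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [10]}
        - {atom: code_in, layer: koppen, codes: [6, 7]}
  - target: 101             # boreal forest
    group: natural
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [10]}
        - {atom: code_in, layer: koppen, codes: [8, 9]}
  - target: 100             # Forest default (Level 1)
    group: default
    when: {atom: code_in, layer: land_cover, codes: [10]}
  # ---- wetlands (inland) ----
  - target: 504             # bogs, marshes, swamps, fens, peatlands
    group: natural
    when: {atom: code_in, layer: wetlands, codes: [3]}
  - target: 503             # shrub-dominated wetlands
    group: natural
    when: {atom: code_in, layer: wetlands, codes: [5]}
  - target: 505             # permanent freshwater lakes
    group: natural
    when: {atom: code_in, layer: wetlands, codes: [1]}
  - target: 500             # Wetlands default (Level 1)
    group: default
    when: {atom: code_in, layer: wetlands, codes: [1, 2, 4]}
  # ---- savanna ----
  - target: 200             # Savanna default (Level 1): tropical herbaceous
    group: default
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [30]}
        - {atom: mask, layer: tropics}
  # ---- shrubland ----
  - target: 304             # temperate shrubland
    group: natural
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [20]}
        - {atom: code_in, layer: koppen, codes: [6, 7]}
  - target: 300             # Shrubland default (Level 1)
    group: default
    when: {atom: code_in, layer: land_cover, codes: [20]}
  # ---- grassland ----
  - target: 404             # temperate grassland
    group: natural
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [30]}
        - {atom: code_in, layer: koppen, codes: [6, 7]}
  - target: 400             # Grassland default (Level 1)
    group: default
    when: {atom: code_in, layer: land_cover, codes: [30]}
  # ---- rocky areas ----
  - target: 600             # bare montane terrain
    group: default
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [60]}
        - {atom: mask, layer: montane}
  # ---- desert ----
  - target: 801             # hot desert
    group: natural
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [60]}
        - {atom: code_in, layer: koppen, codes: [4]}
  - target: 803             # cold desert
    group: natural
    when:
      atom: all
      of:
        - {atom: code_in, layer: land_cover, codes: [60]}
        - {atom: code_in, layer: koppen, codes: [5]}
  - target: 800             # Desert default (Level 1)
    group: default
    when: {atom: code_in, layer: land_cover, codes: [60]}
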