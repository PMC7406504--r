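# Default code tables for the synthetic input stack. Swap in real product
# legends (e.g. Copernicus land cover, GLWD) by editing or replacing this
# file and calling load_legends().
land_cover:
  10: Tree cover
  20: Shrubland
  30: Herbaceous vegetation
  40: Cropland / arable
  50: Urban / built-up
  60: Bare / sparse vegetation
  70: Permanent water body
  80: Herbaceous wetland
koppen:
  1: Af - tropical rainforest
  2: Am - tropical monsoon
  3: Aw - tropical savanna
  4: BWh - hot desert
  5: BSk - cold semi-arid
  6: Cfa - humid subtropical
  7: Csb - warm-summer Mediterranean
  8: Dfb - warm-summer humid continental
  9: Dfc - subarctic
  10: ET - tundra
  11: EF - ice cap
wetland:
  1: Lake
  2: River
  3: Freshwater marsh / floodplain
  4: Swamp forest / flooded forest
  5: Bog / fen / mire (shrub dominated)
field_size:
  1: Very small fields
  2: Small fields
  3: Medium fields
  4: Large fields
forest_management:
  1: Naturally regenerating forest
  2: Planted forest, rotation > 20 years
  3: Short-rotation woody plantation
  4: Agroforestry
  5: Fruit plantation
biome:
  1: Tropical and subtropical forest biome
  2: Temperate / boreal forest biome
  3: Temperate grassland, steppe and meadow biome
  4: Tropical savanna and grassland biome
livestock_region:
  1: Default region
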