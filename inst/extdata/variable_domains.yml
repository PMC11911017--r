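# Natural mathematical domains of the 16 environmental variables.
# "unbounded" means no hard mathematical limit on that side.  Soil pH is
# treated as unbounded: its tails are never reached by field data, so it
# does not act as a truncating bound on any species' gradient.
# `aliases` maps spreadsheet column headers onto the canonical labels and
# can be edited freely.
variables:
  annual_dryness_index:
    lower: 0
    upper: unbounded
    aliases: ["Annual dryness index"]
  terrain_slope:
    lower: 0
    upper: unbounded
    aliases: ["Average slope of the terrain", "Slope"]
  cation_exchange_capacity:
    lower: 0
    upper: unbounded
    aliases: ["Cation exchange capacity of soil", "CEC"]
  elevation:
    lower: 0
    upper: unbounded
    aliases: ["Elevation above sea level", "Elevation"]
  mean_annual_precipitation:
    lower: 0
    upper: unbounded
    aliases: ["Mean annual precipitation", "MAP"]
  mean_annual_temperature:
    lower: unbounded
    upper: unbounded
    aliases: ["Mean annual temperature", "MAT"]
  mean_temp_coldest_month:
    lower: unbounded
    upper: unbounded
    aliases: ["Mean temperature in the coldest month"]
  mean_temp_warmest_month:
    lower: unbounded
    upper: unbounded
    aliases: ["Mean temperature in the warmest month"]
  summer_to_total_precipitation_ratio:
    lower: 0
    upper: 1
    aliases: ["Ratio of summer to total precipitation"]
  soil_organic_carbon:
    lower: 0
    upper: unbounded
    aliases: ["Soil organic-carbon content"]
  soil_ph:
    lower: unbounded
    upper: unbounded
    aliases: ["Soil's pH value", "Soil pH"]
  spring_precipitation:
    lower: 0
    upper: unbounded
    aliases: ["Spring precipitation"]
  summer_precipitation:
    lower: 0
    upper: unbounded
    aliases: ["Summer precipitation"]
  summer_precipitation_balance:
    lower: 0
    upper: unbounded
    aliases: ["Summer precipitation balance"]
  summer_spring_precipitation_balance:
    lower: 0
    upper: unbounded
    aliases: ["Summer/spring precipitation-balance"]
  winter_precipitation:
    lower: 0
    upper: unbounded
    aliases: ["Winter precipitation"]
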