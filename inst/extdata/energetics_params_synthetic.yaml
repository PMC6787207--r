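# Energetics parameters -- SYNTHETIC calibration.
#
# The per-nest fallen-nestling energies, daily energy requirements and the
# reference female-alligator population below are synthetic placeholder
# values chosen on ecological grounds (chick mass at the typical age of
# brood-reduction death, wet-tissue energy density, ectotherm vs endotherm
# field metabolic rates) so that the seasonal energy budget lands in a
# realistic range; they are not transcriptions of any published parameter
# set. Replace them with measured values for real analyses.
#
# Consumption rates are the exact rational stratum proportions from the
# observed consumer table: of known-fate baits, alligators consumed 26/116
# on Ardea-type colonies and 17/21 on Egretta-type colonies; Turkey
# Vultures consumed 59/116 and 2/21. Equal rates are assumed within each
# chick group.
species:
  - name: Great Egret
    energy_per_nest_kJ: 1200
    group: Ardea_like
  - name: White Ibis
    energy_per_nest_kJ: 350
    group: Ardea_like
  - name: Wood Stork
    energy_per_nest_kJ: 1800
    group: Ardea_like
  - name: Egretta_group
    energy_per_nest_kJ: 250
    group: Egretta_like
scavengers:
  - name: alligator_adult_female
    daily_energy_requirement_kJ: 300
    season_days: 60
    reference_population: 1131
  - name: turkey_vulture_adult
    daily_energy_requirement_kJ: 800
    season_days: 60
consumption_rates:
  alligator_adult_female:
    Ardea_like: 26/116
    Egretta_like: 17/21
  turkey_vulture_adult:
    Ardea_like: 59/116
    Egretta_like: 2/21
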