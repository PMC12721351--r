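# Transport emission factors, kg CO2e per statute mile.
#
# drive: gasoline/petrol vehicle, "large car" category, UK government
#   greenhouse-gas conversion basis.
# charter: whole-flight short-haul (within-Europe basis) dedicated charter
#   estimate assuming two people travelling per procurement (~200 kg added
#   weight). Whole-aircraft accounting: the flight exists only for the
#   organ, so the full flight footprint is attributed to it.
# commercial: zero - the organ rides on a scheduled flight that operates
#   anyway.
#
# These are configurable inputs, not constants; supply your own factor file
# (and vintage) for audited analyses.
drive_kg_per_mile: 0.44
charter_kg_per_mile: 2.06
commercial_kg_per_mile: 0.0
source: UK DESNZ-style greenhouse-gas conversion estimates
vintage: "2023"
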