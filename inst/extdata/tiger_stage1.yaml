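# Stage-1 continent-island demography: four subspecies diverging recently
# from a large Asian metapopulation with weak continued immigration.
# Divergence times follow published point estimates (in generations at 5
# years per generation); sizes, migration rates and bottleneck parameters
# are illustrative desk-scale values chosen to reproduce the observed
# differentiation regime (pairwise FST roughly 0.15-0.35, strongest drift
# in AMU and SUM). See the methods vignette for the calibration rationale.
mutation_rate: 3.5e-9
generation_time: 5.0
metapopulations:
  - name: ASIA
    diploid_size: 20000
populations:
  - name: SUM            # Sumatra: founder event + strong recent bottleneck
    diploid_size: 2500
    sample_size: 3
    divergence_time: 1840
    migration_rate: 4.0e-5
    parent: ASIA
  - name: BEN            # Bengal: founder event, large recent size
    diploid_size: 6000
    sample_size: 3
    divergence_time: 1680
    migration_rate: 4.0e-5
    parent: ASIA
  - name: MAL            # Malayan: no founder effect, no recent bottleneck
    diploid_size: 5000
    sample_size: 4
    divergence_time: 1500
    migration_rate: 4.0e-5
    parent: ASIA
  - name: AMU            # Amur: strong recent bottleneck
    diploid_size: 3000
    sample_size: 3
    divergence_time: 1500
    migration_rate: 4.0e-5
    parent: ASIA
bottlenecks:
  - population: SUM      # founder effect at the separation from Asia
    start_time: 1740
    duration: 100
    bottleneck_size: 400
  - population: BEN      # founder effect at the separation from Asia
    start_time: 1580
    duration: 100
    bottleneck_size: 1500
  - population: SUM      # recent contraction
    start_time: 10
    duration: 20
    bottleneck_size: 100
  - population: AMU      # recent contraction
    start_time: 10
    duration: 20
    bottleneck_size: 150
  - population: ASIA     # ancient bottleneck of the metapopulation
    start_time: 46800
    duration: 400
    bottleneck_size: 500
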