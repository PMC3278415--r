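# Assumed pairwise rank correlations between uncertain model parameters.
#
# Identifiers name catalog parameter columns.  The prefix `stove.` is a
# placeholder that is expanded to every stove in the catalog that carries
# the named field; a pair in which both sides carry the prefix is applied
# within each stove (e.g. a stove's own cost against its own lifespan).
# Each unordered pair is listed once; the diagonal is implicitly 1.
#
# The assembled matrix is not guaranteed to be positive semidefinite and
# is repaired by eigenvalue clipping before sampling.

correlations:
  # stove cost
  - {a: stove.cc, b: stove.lifespan, rho: 0.7}    # durable stoves cost more
  - {a: stove.cc, b: w, rho: 0.5}                 # costlier where wages are high
  - {a: stove.cc, b: stove.eps_t, rho: -0.5}      # time-efficient stoves cost more
  - {a: stove.cc, b: fuelt0, rho: 0.5}
  - {a: stove.cc, b: stove.eta_ari, rho: 0.5}     # cleaner stoves cost more
  - {a: stove.cc, b: stove.eta_copd, rho: 0.5}
  - {a: stove.cc, b: cfr_alri, rho: 0.5}          # costlier where health care is poor
  - {a: stove.cc, b: drate_copd, rho: 0.5}
  # stove lifespan
  - {a: stove.lifespan, b: cm, rho: 0.5}          # better upkeep lengthens life
  - {a: stove.lifespan, b: cookt0, rho: -0.5}     # heavier use shortens life
  - {a: stove.lifespan, b: stove.eps_t, rho: -0.5}
  # program cost
  - {a: cp, b: inc_ari, rho: 0.5}
  - {a: cp, b: prev_copd, rho: 0.5}
  - {a: cp, b: cfr_alri, rho: 0.5}
  - {a: cp, b: drate_copd, rho: 0.5}
  - {a: cp, b: w, rho: 0.5}
  # maintenance cost
  - {a: cm, b: cookt0, rho: 0.5}
  - {a: cm, b: w, rho: 0.5}
  # baseline cooking time
  - {a: cookt0, b: fuelt0, rho: -0.5}
  - {a: cookt0, b: vt, rho: -0.5}
  # solid-fuel prices
  - {a: price.wood, b: w, rho: 0.5}
  - {a: price.charcoal, b: w, rho: 0.5}
  # shadow value of time
  - {a: vt, b: price.wood, rho: 0.5}
  - {a: vt, b: price.charcoal, rho: 0.5}
  - {a: vt, b: w, rho: 0.5}
  # health parameters
  - {a: inc_ari, b: w, rho: -0.5}
  - {a: coi_ari, b: w, rho: 0.5}
  - {a: coi_copd, b: w, rho: 0.5}
  - {a: vsl, b: w, rho: 0.7}
  - {a: cfr_alri, b: w, rho: -0.5}
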