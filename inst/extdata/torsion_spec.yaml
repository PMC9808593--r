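# Class-conditional torsion-angle distributions for the synthetic generator.
#
# One wrapped-normal component per angle per subpopulation (mean/sd in
# degrees, sampled as rnorm %% 360). Parameters marked "reported" place
# ~95% of their mass inside a range documented for the corresponding real
# structure family; parameters marked "filled" are canonical backbone
# values for angles no range is documented for — they are deliberately
# broad/overlapping so they cannot drive classification by construction.
# Default per-class counts are the curated data-set sizes (125/88/76/175).
# Edit freely; validate_spec() checks the invariants.
classes:
  LHG4:
    label: 0
    count: 125
    subpopulations:
      - name: tract_g1            # first guanosine of each 5'->3' tract
        base: G
        tract_position: 1
        weight: 0.5
        angles:
          alpha:   {mean: 180.0, sd: 12.5}   # reported: 150-200, centred 180
          beta:    {mean: 190.0, sd: 15.0}   # reported: above 150
          gamma:   {mean: 55.0,  sd: 15.0}   # filled
          delta:   {mean: 135.0, sd: 12.0}   # filled
          epsilon: {mean: 195.0, sd: 10.0}   # reported bimodal: cluster 1
          zeta:    {mean: 60.0,  sd: 12.0}   # reported bimodal: cluster 1
          chi:     {mean: 250.0, sd: 12.0}   # anti (all LHG4 bases are anti)
      - name: tract_g2            # second guanosine of each tract
        base: G
        tract_position: 2
        weight: 0.5
        angles:
          alpha:   {mean: 180.0, sd: 12.5}
          beta:    {mean: 190.0, sd: 15.0}
          gamma:   {mean: 55.0,  sd: 15.0}
          delta:   {mean: 135.0, sd: 12.0}
          epsilon: {mean: 260.0, sd: 10.0}   # reported bimodal: cluster 2
          zeta:    {mean: 170.0, sd: 12.0}   # reported bimodal: cluster 2
          chi:     {mean: 250.0, sd: 12.0}
  RHG4:
    label: 1
    count: 88
    subpopulations:
      - name: tetrad_g
        base: G
        weight: 1.0
        angles:
          alpha:   {mean: 300.0, sd: 18.0}   # reported: 250-325, peak 300
          beta:    {mean: 140.0, sd: 30.0}   # filled; broad, mostly < 150
          gamma:   {mean: 55.0,  sd: 20.0}   # filled
          delta:   {mean: 140.0, sd: 15.0}   # filled
          epsilon: {mean: 210.0, sd: 20.0}   # filled, unimodal
          zeta:    {mean: 260.0, sd: 25.0}   # filled, unimodal
          chi:     {mean: 250.0, sd: 15.0}   # anti
  ZDNA:
    label: 0
    count: 76
    subpopulations:
      - name: syn_g               # syn half of the syn-anti dinucleotide step
        base: G
        weight: 0.5
        angles:
          alpha:   {mean: 65.0,  sd: 15.0}   # reported: guanosine alpha < 200
          beta:    {mean: 185.0, sd: 15.0}   # filled
          gamma:   {mean: 180.0, sd: 15.0}   # filled (trans in syn-G)
          delta:   {mean: 100.0, sd: 12.0}   # filled
          epsilon: {mean: 245.0, sd: 15.0}   # filled
          zeta:    {mean: 75.0,  sd: 15.0}   # filled
          chi:     {mean: 60.0,  sd: 12.0}   # syn guanosine
      - name: anti_c
        base: C
        weight: 0.5
        angles:
          alpha:   {mean: 180.0, sd: 12.0}   # reported: 150-200, peak 180
          beta:    {mean: 230.0, sd: 15.0}   # filled
          gamma:   {mean: 55.0,  sd: 12.0}   # filled
          delta:   {mean: 140.0, sd: 12.0}   # filled
          epsilon: {mean: 265.0, sd: 15.0}   # filled
          zeta:    {mean: 290.0, sd: 15.0}   # filled
          chi:     {mean: 240.0, sd: 12.0}   # anti cytidine
  BDNA:
    label: 1
    count: 175
    subpopulations:
      - name: mixed
        base: [A, C, G, T]
        weight: 1.0
        angles:
          alpha:   {mean: 300.0, sd: 25.0}   # reported: 240-360
          beta:    {mean: 160.0, sd: 30.0}   # filled
          gamma:   {mean: 55.0,  sd: 20.0}   # filled
          delta:   {mean: 130.0, sd: 20.0}   # filled
          epsilon: {mean: 190.0, sd: 20.0}   # filled
          zeta:    {mean: 265.0, sd: 20.0}   # filled
          chi:     {mean: 250.0, sd: 15.0}   # filled
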