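# Frozen chemistry oracle: masses, DBE, AI_mod and ratios computed
# independently from the published monoisotopic mass table.
hand_checked_formulae <- list(
  list(f = "CH4", mass = 16.0313001, dbe = 0, ai = 0, hc = 4, oc = 0),
  list(f = "C2H6O", mass = 46.0418648, dbe = 0, ai = 0, hc = 3, oc = 0.5),
  list(f = "C6H6", mass = 78.0469502, dbe = 4, ai = 0.6666666667, hc = 1, oc = 0),
  list(f = "C6H12O6", mass = 180.0633881, dbe = 1, ai = 0, hc = 2, oc = 1),
  list(f = "C16H10", mass = 202.0782503, dbe = 12, ai = 0.75, hc = 0.625, oc = 0),
  list(f = "C9H10O5", mass = 198.0528234, dbe = 5, ai = 0.3846153846,
       hc = 1.1111111111, oc = 0.5555555556),
  list(f = "C7H6O2", mass = 122.0367794, dbe = 5, ai = 0.6666666667,
       hc = 0.8571428571, oc = 0.2857142857),
  list(f = "C2H4O2", mass = 60.0211294, dbe = 1, ai = 0, hc = 2, oc = 1),
  list(f = "C10H8", mass = 128.0626003, dbe = 7, ai = 0.7, hc = 0.8, oc = 0),
  list(f = "C14H10", mass = 178.0782503, dbe = 10, ai = 0.7142857143,
       hc = 0.7142857143, oc = 0),
  list(f = "C6H5NO2", mass = 123.0320284, dbe = 5, ai = 0.875,
       hc = 0.8333333333, oc = 0.3333333333),
  list(f = "C8H9NO2", mass = 151.0633285, dbe = 5, ai = 0.5833333333,
       hc = 1.125, oc = 0.25),
  list(f = "C3H7NO2", mass = 89.0476785, dbe = 1, ai = 0,
       hc = 2.3333333333, oc = 0.6666666667),
  list(f = "C6H13NO2", mass = 131.0946287, dbe = 1, ai = 0,
       hc = 2.1666666667, oc = 0.3333333333),
  list(f = "C12H22O11", mass = 342.1162115, dbe = 2, ai = 0,
       hc = 1.8333333333, oc = 0.9166666667),
  list(f = "C2H6OS", mass = 78.0139355, dbe = 0, ai = 0, hc = 3, oc = 0.5),
  list(f = "C10H14N2", mass = 162.1156985, dbe = 5, ai = 0.5, hc = 1.4, oc = 0),
  list(f = "C3H9O4P", mass = 140.0238453, dbe = 0, ai = 0, hc = 3,
       oc = 1.3333333333),
  list(f = "C27H46O", mass = 386.3548661, dbe = 5, ai = 0.1698113208,
       hc = 1.7037037037, oc = 0.037037037),
  list(f = "C7H6O3S", mass = 170.0037647, dbe = 5, ai = 0.5555555556,
       hc = 0.8571428571, oc = 0.4285714286)
)
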