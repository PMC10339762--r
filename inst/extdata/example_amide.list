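     Assignment         w1         w2          Height
         C11N-H   123.0367     8.9425    1.000000e+00
         S20N-H   114.2210     7.8812    9.500000e-01
         R21N-H   119.4402     8.5127    1.020000e+00
         L24N-H   126.8890     8.1204    9.800000e-01
         E25N-H   117.9034     8.7519    1.010000e+00
         I53N-H   121.3049     8.4512    1.000000e+00
         C54N-H   110.5521     9.0218    9.700000e-01
         M66N-H   124.7716     7.6620    9.900000e-01
         Q69N-H   118.3345     8.2901    1.000000e+00
              ?   112.5000     7.3400    4.100000e-01
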