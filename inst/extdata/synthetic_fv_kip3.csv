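# kinslip_version: 0.1.0
# note: synthetic data generated from the kip3_table1 preset with seeded Gaussian noise (SD 2 nm/s); not an experimental measurement
# atp: saturating
# slip_included: FALSE
# preset: kip3_table1
force_pN,velocity_nm_per_s,sd_nm_per_s
-10,-333.891198422363,2
-9.5,-324.513340956287,2
-9,-322.771932794739,2
-8.5,-315.241401344063,2
-8,-305.952146077542,2
-7.5,-296.068459356081,2
-7,-277.833717727783,2
-6.5,-263.175340487105,2
-6,-246.059191940887,2
-5.5,-229.396187293534,2
-5,-206.923787808516,2
-4.5,-183.397783588331,2
-4,-157.397353700423,2
-3.5,-129.957700373697,2
-3,-103.449565782857,2
-2.5,-73.9651164044898,2
-2,-49.0273202199437,2
-1.5,-22.4953362153863,2
-1,6.05990808366629,2
-0.5,27.4124417797322,2
0,44.7419124549133,2
0.5,66.8998577302528,2
1,85.3231854851095,2
1.5,99.4697755656118,2
2,109.551014809641,2
2.5,120.287753102021,2
3,129.545365258557,2
3.5,142.340407638998,2
4,147.240072948561,2
4.5,147.93242407375,2
5,154.383895369084,2
5.5,157.963564512048,2
6,159.618989807899,2
6.5,161.325693926805,2
7,165.782373875216,2
7.5,171.117169193495,2
8,166.52886752054,2
8.5,174.680809483409,2
9,169.213702071101,2
9.5,174.275156031677,2
10,169.335540040871,2
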