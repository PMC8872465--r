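# RNA/RNA Watson-Crick nearest-neighbor stacking parameters
# Freier et al. (1986) Proc Natl Acad Sci USA 83:9373-9377 (1 M NaCl)
# stack: 5'->3' dinucleotide on the strand of interest, paired with its
# perfect complement. The 10 published values expand to 16 keys by
# reverse-complement symmetry.
# dH_kcal: enthalpy change, kcal/mol; dS_cal: entropy change, cal/(mol K)
stack	dH_kcal	dS_cal
AA	-6.6	-18.4
UU	-6.6	-18.4
AU	-5.7	-15.5
UA	-8.1	-22.6
CA	-10.5	-27.8
UG	-10.5	-27.8
GU	-10.2	-26.2
AC	-10.2	-26.2
CU	-7.6	-19.2
AG	-7.6	-19.2
GA	-13.3	-35.5
UC	-13.3	-35.5
CG	-8.0	-19.4
GC	-14.2	-34.9
GG	-12.2	-29.7
CC	-12.2	-29.7
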