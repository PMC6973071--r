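# SYNTHETIC stand-in Karplus parameter set (provenance header).
#
# These coefficients are NOT a transcription of any published relation. The
# quantitative 1H-19F Karplus relation for 2'-fluoro sugars used in the
# source literature is not reproducible offline; this set uses magnitudes
# typical of furanose 3J(H,H) (~10 Hz ceiling) and 3J(H,F) (~30-45 Hz
# ceiling) couplings so that the package's simulation and grid-inversion
# machinery behaves realistically. Replace with a literature set (same
# columns) for quantitative work.
#
# Columns: path label; Karplus A, B, C (Hz) in J = A cos^2(theta) +
# B cos(theta) + C; substituent map theta = a * nu_k + b (degrees) with
# nu = index k of the governing endocyclic torsion.
path	A	B	C	a	b	nu
H1'-H2'	10.2	-0.8	0	1.03	121.4	1
H2'-H3'	10.2	-0.8	0	1.06	2.4	2
H3'-H4'	10.2	-0.8	0	1.06	-124.0	3
F2'-H1'	31.0	-11.0	3.0	1.03	1.4	1
F2'-H3'	31.0	-11.0	3.0	1.06	122.4	2
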