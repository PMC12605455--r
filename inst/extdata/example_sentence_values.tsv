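word	cosine	dissimilarity	informativeness
even	0.990	0.010	-4.563
though	0.994	0.006	-5.150
most	0.987	0.013	-4.346
of	0.999	0.001	-6.698
his	0.995	0.005	-5.329
inventions	0.971	0.029	-3.542
were	0.997	0.003	-5.801
not	0.976	0.024	-3.745
actually	0.992	0.008	-4.864
built	0.992	0.008	-4.833
in	0.998	0.002	-6.276
his	0.998	0.002	-6.229
lifetime	0.975	0.025	-3.692
many	0.994	0.006	-5.042
of	>0.999	<0.001	-8.262
today’s	0.994	0.006	-5.041
modern	0.988	0.012	-4.420
machines	0.949	0.051	-2.976
can	0.982	0.018	-4.025
be	0.999	0.001	-7.511
traced	0.991	0.009	-4.747
back	0.986	0.014	-4.299
to	>0.999	<0.001	-8.017
some	0.996	0.004	-5.489
of	0.999	0.001	-7.260
his	0.999	0.001	-6.748
original	0.984	0.016	-4.139
designs	0.987	0.013	-4.356
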