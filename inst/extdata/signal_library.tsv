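# Per-device blockade statistics for single amino acids, homopeptides and
# phosphotyrosine in MoS2 nanopores. units: "nA" rows are absolute blockade
# dI; "relative" rows are dI/I0. charge_sign is the molecular charge at
# pH 7.8 (K and R positive; the rest negative); the driving bias has the
# opposite sign. Two rows with the same (label, device) form a bimodal
# two-component mixture (equal weights; the split reflects pore-entry
# orientation). "Device #10b" is a second measurement session on Device #10
# (sub-Dalton N/L pair). Dwell parameters are generative defaults, not
# measured values.
label	device	component	weight	mean	sd	units	charge_sign	dwell_median_s	dwell_sigma_log
G	Device #3	1	1.0	0.129	0.021	nA	-1	5e-4	0.6
GG	Device #3	1	1.0	0.127	0.016	nA	-1	5e-4	0.6
GGG	Device #3	1	1.0	0.127	0.021	nA	-1	5e-4	0.6
G	Device #4	1	1.0	0.229	0.016	relative	-1	5e-4	0.6
A	Device #4	1	1.0	0.295	0.021	relative	-1	5e-4	0.6
K	Device #5	1	1.0	0.127	0.028	relative	1	5e-4	0.6
R	Device #5	1	1.0	0.154	0.023	relative	1	5e-4	0.6
Y	Device #5	1	1.0	0.106	0.012	relative	-1	5e-4	0.6
p-Y	Device #5	1	1.0	0.128	0.019	relative	-1	5e-4	0.6
D	Device #6	1	1.0	0.273	0.035	relative	-1	5e-4	0.6
E	Device #6	1	1.0	0.252	0.042	relative	-1	5e-4	0.6
H	Device #6	1	0.5	0.298	0.026	relative	-1	5e-4	0.6
H	Device #6	2	0.5	0.389	0.068	relative	-1	5e-4	0.6
A	Device #7	1	1.0	0.058	0.009	relative	-1	5e-4	0.6
V	Device #7	1	1.0	0.065	0.009	relative	-1	5e-4	0.6
L	Device #8	1	1.0	0.230	0.076	relative	-1	5e-4	0.6
I	Device #8	1	1.0	0.284	0.065	relative	-1	5e-4	0.6
M	Device #8	1	1.0	0.329	0.069	relative	-1	5e-4	0.6
S	Device #9	1	1.0	0.228	0.033	relative	-1	5e-4	0.6
T	Device #9	1	1.0	0.327	0.048	relative	-1	5e-4	0.6
N	Device #10	1	1.0	0.241	0.031	relative	-1	5e-4	0.6
Q	Device #10	1	1.0	0.268	0.024	relative	-1	5e-4	0.6
N	Device #10b	1	1.0	0.218	0.042	relative	-1	5e-4	0.6
L	Device #10b	1	1.0	0.360	0.078	relative	-1	5e-4	0.6
F	Device #11	1	1.0	0.212	0.052	relative	-1	5e-4	0.6
Y	Device #11	1	1.0	0.241	0.054	relative	-1	5e-4	0.6
W	Device #11	1	1.0	0.284	0.047	relative	-1	5e-4	0.6
G	Device #12	1	0.5	0.257	0.019	relative	-1	5e-4	0.6
G	Device #12	2	0.5	0.356	0.077	relative	-1	5e-4	0.6
C	Device #12	1	1.0	0.326	0.053	relative	-1	5e-4	0.6
P	Device #12	1	1.0	0.349	0.060	relative	-1	5e-4	0.6
D	Device #13	1	1.0	0.072	0.006	relative	-1	5e-4	0.6
N	Device #13	1	1.0	0.083	0.006	relative	-1	5e-4	0.6
E	Device #14	1	1.0	0.300	0.037	relative	-1	5e-4	0.6
Q	Device #14	1	1.0	0.314	0.031	relative	-1	5e-4	0.6
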