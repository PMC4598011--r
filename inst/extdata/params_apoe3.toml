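# glymphsim model parameter preset: ApoE2/E3 defaults
# flat key = value dialect; keys are exactly the model parameter field names
# units in comments

d = 0.01                 # natural neuron loss, fraction/year
k1 = 0.034               # amyloid-stimulated extra neuron loss, fraction/year
k2 = 0.01                # endothelial senescence, fraction/year
k3 = 16000               # Abeta40 generation, molecules/neuron/day
k8 = 3000                # Abeta42 generation, molecules/neuron/day
k4 = 1.5                 # stimulated-generation multiplier, dimensionless
k5 = 1400                # microglial Abeta40 uptake, molecules/microglia/day
k11 = 200                # microglial Abeta42 uptake, molecules/microglia/day
k6 = 0.4                 # LRP-1 transport, fraction/day (ApoE4: 0.12)
k7 = 0.004               # Abeta40 vessel-wall deposition, fraction/day
k9a = 0.002              # Abeta42 vessel-wall deposition, fraction/day
k7a = 0.001              # Abeta40 parenchymal deposition, fraction/day
k9 = 0.001               # Abeta42 parenchymal deposition, fraction/day
k10 = 0.01               # LRP-1 receptor loss, fraction/year (= k2)
k12 = 7.3e-5             # microglial conversion to dystrophy, fraction/day
N0 = 5275                # neurons per mm^3
M0 = 4500                # microglia per mm^3
EC0 = 22050              # endothelial cells per mm^3 (21 x 21 capillaries x 50)
LRP0 = 9.3e11            # LRP-1 receptors per mm^3
C1_0 = 450               # initial parenchymal Abeta40, pg/mL
C4_0 = 70                # initial parenchymal Abeta42, pg/mL
pvs_init_fraction = 0.1  # initial perivascular amyloid / parenchymal amyloid
v0 = 0.2946              # baseline ISF bulk velocity, mm/day (calibrated)
k_exit = 0.1304          # perivascular glymphatic exit, fraction/day (calibrated)
theta_k1 = 20            # neuron-loss trigger, multiple of initial Abeta40
mw40 = 4330              # Abeta40 monomer mass, Da
mw42 = 4514              # Abeta42 monomer mass, Da
model_volume = 1         # mm^3
segment_length = 1       # mm, convective path length
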