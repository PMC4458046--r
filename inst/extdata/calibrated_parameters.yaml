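# Calibrated rate, saturation and proportionality constants for the
# three-compartment CD8+ T cell / B16F10 tumor model, plus the fixed
# physical constants (compartment volumes, cell sizes, epsilon offset).
# Units follow the model convention: densities in cells per mm^3,
# tumor cells in counts, adenovirus in RLU per mm^3, cytokines in
# moles per mm^3, time in days.
kd1: 3.809e-3      # day^-1, naive CD8+ T cell natural death
kd2: 0.364         # day^-1, adenovirus decay
kd3: 1.80e-2       # day^-1, blood effector natural death
kd4: 2.08e-6       # day^-1, tumor cell natural death
kd5: 0.800         # day^-1, tumor effector natural death
kd6: 0.082         # day^-1, IFN-gamma degradation
kd7: 3.10e-6       # day^-1, TNF-alpha degradation
kp1: 12.017        # day^-1, lymph-node effector proliferation
kp2: 0.5           # day^-1, tumor cell proliferation
kp3: 5.73e-6       # day^-1, tumor effector local proliferation
a12: 5.706         # day^-1, T cell flow lymph node -> blood
a21: 3.540e-3      # day^-1, T cell flow blood -> lymph node
a23: 5.546e-2      # day^-1, T cell flow blood -> tumor
a32: 6.89e-18      # day^-1, T cell flow tumor -> blood
c1: 2.719e-4       # cell mm^-3 day^-1, naive T cell production
c2: 0.5263         # day^-1, naive -> lymph-node effector transfer
c3: 0.8759         # day^-1, MHCI- -> MHCI+ conversion
c4: 2.49e-13       # mm^3 day^-1, effector-mediated MHCI+ kill
alpha: 6.520e10    # (cell mm^-3)^2, lymph-node effector checkpoint saturation
k1: 3.69e-9        # moles mm^-3, IFN-gamma saturation
k2: 6.924e6        # moles mm^-3, TNF-alpha saturation
k3: 2.634e-4       # moles day^-1 cell^-1, constitutive TNF-alpha production
kc1: 7.295e8       # moles day^-1 cell^-1, IFN-gamma production
kc2: 9.939e8       # moles day^-1 cell^-1, autocrine TNF-alpha production
gamma: 2.905e3     # RLU mm^-3, adenovirus saturation
beta1: 8.79e-6     # AU, TCR-alpha gene-expression proportionality (stored, unused)
r2: 3.34e-10       # cell^-1 day^-1, logistic crowding
vol_b: 1.4e3       # mm^3, blood compartment volume
vol_ln: 0.25       # mm^3, lymph node compartment volume
s_t: 6.0e-7        # mm^3, B16F10 tumor cell volume
v_i: 1.0e-7        # mm^3, effector T cell volume
epsilon: 1.0e-3    # small positive offset (volume and count roles)
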