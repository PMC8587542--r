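# Body segment inertial parameter coefficients, v1.
# After the adjusted regression tables of Dumas, Cheze & Verriest (2007),
# J Biomech 40:543-553 (with corrigendum), simplified for this package:
#   - head and neck merged into a single "head" segment,
#   - transverse centre-of-mass offsets neglected (longitudinal only),
#   - inertia reduced to principal-axis radii of gyration.
# Segment length fractions of stature follow Drillis & Contini (1966).
# Columns:
#   mass_frac   segment mass as fraction of total body mass (renormalised
#               downstream so the 15 segments sum exactly to body mass)
#   length_frac segment length as fraction of stature
#   com_frac    longitudinal CoM position as fraction of segment length,
#               measured from the proximal joint along the segment axis
#   rg_x,rg_y,rg_z  radii of gyration about the segment-frame axes through
#               the CoM, as fractions of segment length
segment,sex,mass_frac,length_frac,com_frac,rg_x,rg_y,rg_z
pelvis,male,0.142,0.093,0.30,0.30,0.30,0.30
torso,male,0.333,0.288,0.45,0.30,0.28,0.25
head,male,0.067,0.182,0.50,0.28,0.30,0.24
upper_arm,male,0.024,0.186,0.45,0.29,0.27,0.16
forearm,male,0.017,0.146,0.42,0.28,0.27,0.12
hand,male,0.006,0.108,0.36,0.26,0.25,0.16
thigh,male,0.123,0.245,0.43,0.32,0.32,0.15
shank,male,0.048,0.246,0.42,0.28,0.28,0.10
foot,male,0.012,0.152,0.44,0.17,0.36,0.35
pelvis,female,0.146,0.093,0.30,0.31,0.31,0.30
torso,female,0.304,0.288,0.45,0.31,0.29,0.27
head,female,0.067,0.182,0.50,0.29,0.30,0.25
upper_arm,female,0.022,0.186,0.45,0.29,0.28,0.16
forearm,female,0.013,0.146,0.42,0.28,0.27,0.12
hand,female,0.005,0.108,0.36,0.27,0.26,0.17
thigh,female,0.146,0.245,0.43,0.33,0.33,0.16
shank,female,0.045,0.246,0.42,0.28,0.28,0.10
foot,female,0.010,0.152,0.44,0.17,0.36,0.35
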