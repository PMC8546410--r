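# Pairwise residue-residue contact energies (dimensionless model units, RT-like).
# Derived from the per-residue contact-energy (hydrophobicity) scale of
# Miyazawa & Jernigan, Macromolecules 18:534-552 (1985), via the centered
# one-body (quasichemical) approximation e_ij = -s*((h_i-h0) + (h_j-h0))/2,
# with s and h0 anchored so that the two canonical strong pairs match the
# 1996 tabulation: e(C,C) = -5.44 and e(F,F) = -7.26. Hydrophobic pairs are
# attractive (negative), polar-polar pairs near zero or repulsive. Values
# are solvent-referenced, so the default residue-solvent term is 0. Any
# symmetric 20x20 table may be substituted via energy_params().
aa,A,R,N,D,C,Q,E,G,H,I,L,K,M,F,P,S,T,W,Y,V
A,-1.138,-0.187,0.202,0.301,-3.289,0.070,0.252,-0.435,-0.948,-4.034,-3.736,0.831,-4.133,-4.199,0.070,-0.112,-0.443,-3.066,-1.601,-3.041
R,-0.187,0.765,1.153,1.253,-2.338,1.021,1.203,0.516,0.003,-3.082,-2.784,1.782,-3.182,-3.248,1.021,0.839,0.508,-2.114,-0.650,-2.090
N,0.202,1.153,1.542,1.641,-1.949,1.410,1.592,0.905,0.392,-2.693,-2.396,2.171,-2.793,-2.859,1.410,1.228,0.897,-1.726,-0.261,-1.701
D,0.301,1.253,1.641,1.741,-1.850,1.509,1.691,1.004,0.492,-2.594,-2.296,2.270,-2.693,-2.760,1.509,1.327,0.996,-1.626,-0.162,-1.601
C,-3.289,-2.338,-1.949,-1.850,-5.440,-2.081,-1.899,-2.586,-3.099,-6.185,-5.887,-1.320,-6.284,-6.350,-2.081,-2.263,-2.594,-5.217,-3.752,-5.192
Q,0.070,1.021,1.410,1.509,-2.081,1.277,1.459,0.773,0.260,-2.826,-2.528,2.039,-2.925,-2.991,1.277,1.095,0.765,-1.858,-0.394,-1.833
E,0.252,1.203,1.592,1.691,-1.899,1.459,1.641,0.955,0.442,-2.644,-2.346,2.221,-2.743,-2.809,1.459,1.277,0.947,-1.676,-0.212,-1.651
G,-0.435,0.516,0.905,1.004,-2.586,0.773,0.955,0.268,-0.245,-3.330,-3.033,1.534,-3.430,-3.496,0.773,0.591,0.260,-2.363,-0.898,-2.338
H,-0.948,0.003,0.392,0.492,-3.099,0.260,0.442,-0.245,-0.758,-3.843,-3.546,1.021,-3.943,-4.009,0.260,0.078,-0.253,-2.875,-1.411,-2.851
I,-4.034,-3.082,-2.693,-2.594,-6.185,-2.826,-2.644,-3.330,-3.843,-6.929,-6.631,-2.065,-7.028,-7.095,-2.826,-3.008,-3.339,-5.961,-4.497,-5.936
L,-3.736,-2.784,-2.396,-2.296,-5.887,-2.528,-2.346,-3.033,-3.546,-6.631,-6.333,-1.767,-6.731,-6.797,-2.528,-2.710,-3.041,-5.663,-4.199,-5.639
K,0.831,1.782,2.171,2.270,-1.320,2.039,2.221,1.534,1.021,-2.065,-1.767,2.800,-2.164,-2.230,2.039,1.857,1.526,-1.097,0.367,-1.072
M,-4.133,-3.182,-2.793,-2.693,-6.284,-2.925,-2.743,-3.430,-3.943,-7.028,-6.731,-2.164,-7.128,-7.194,-2.925,-3.107,-3.438,-6.060,-4.596,-6.036
F,-4.199,-3.248,-2.859,-2.760,-6.350,-2.991,-2.809,-3.496,-4.009,-7.095,-6.797,-2.230,-7.194,-7.260,-2.991,-3.173,-3.504,-6.127,-4.662,-6.102
P,0.070,1.021,1.410,1.509,-2.081,1.277,1.459,0.773,0.260,-2.826,-2.528,2.039,-2.925,-2.991,1.277,1.095,0.765,-1.858,-0.394,-1.833
S,-0.112,0.839,1.228,1.327,-2.263,1.095,1.277,0.591,0.078,-3.008,-2.710,1.857,-3.107,-3.173,1.095,0.913,0.583,-2.040,-0.576,-2.015
T,-0.443,0.508,0.897,0.996,-2.594,0.765,0.947,0.260,-0.253,-3.339,-3.041,1.526,-3.438,-3.504,0.765,0.583,0.252,-2.371,-0.907,-2.346
W,-3.066,-2.114,-1.726,-1.626,-5.217,-1.858,-1.676,-2.363,-2.875,-5.961,-5.663,-1.097,-6.060,-6.127,-1.858,-2.040,-2.371,-4.993,-3.529,-4.968
Y,-1.601,-0.650,-0.261,-0.162,-3.752,-0.394,-0.212,-0.898,-1.411,-4.497,-4.199,0.367,-4.596,-4.662,-0.394,-0.576,-0.907,-3.529,-2.065,-3.504
V,-3.041,-2.090,-1.701,-1.601,-5.192,-1.833,-1.651,-2.338,-2.851,-5.936,-5.639,-1.072,-6.036,-6.102,-1.833,-2.015,-2.346,-4.968,-3.504,-4.944
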