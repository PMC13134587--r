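g_Na: 11.0
g_CaL: 0.4
g_Kr: 0.12
g_Ks: 0.12
g_K1: 0.2
g_leak: 0.012
s_Kr: 1.0
s_Ks: 1.0
s_CaL: 1.0
E_Na: 65.0
E_K: -87.0
E_Ca: 52.0
E_leak: -30.0
C_m: 1.0
m_vh: -40.0
m_k: 6.0
m_tau0: 0.12
m_tauA: 0.4
m_tauV: -40.0
m_tauS: 25.0
h_vh: -68.0
h_k: 6.5
h_tau0: 1.0
h_tauA: 14.0
h_tauV: -67.0
h_tauK: 8.0
d_vh: -10.0
d_k: 6.2
d_tau0: 1.0
d_tauA: 2.0
d_tauV: -10.0
d_tauS: 30.0
f_vh: -27.0
f_k: 7.0
f_tau0: 180.0
f_tauA: 400.0
f_tauV: -25.0
f_tauS: 30.0
xr_vh: -14.0
xr_k: 7.0
xr_tau0: 80.0
xr_tauA: 350.0
xr_tauV: -20.0
xr_tauS: 25.0
rkr_vh: -15.0
rkr_k: 22.0
xs_vh: 4.0
xs_k: 12.0
xs_tau0: 250.0
xs_tauA: 200.0
xs_tauV: 10.0
xs_tauS: 40.0
k1_k: 0.07
k1_vh: -80.0
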