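# trichofe default configuration (calibrated; see the methods vignette)
forcing.mode = constant
forcing.I_const = 90
forcing.I_max = 200
forcing.day_length_s = 43200
environment.Fe_prime_pM = 40
environment.O2_ambient = 0.21
case.mode = dynamic
case.fFe0PS = 0.75
case.fFe0NF = 0.15
uptake.Q_max = 500
uptake.K_Fe = 320
uptake.f_sto_max = 0.65
uptake.K_sto = 300
uptake.f_maint = 0.1
photo.vPETmax = 0.002
photo.kFePS = 30
photo.alpha_I = 0.022
photo.beta = 12000
nfix.kFeNF = 100
nfix.kO2NF = 0.05
nfix.N_max = 0.105
nfix.kCS = 0.1
energy.e_per_O2 = 4
energy.nadph_per_e_LPET = 0.5
energy.atp_per_e_LPET = 0.75
energy.atp_per_e_AET = 1
energy.atp_per_C_CF = 4
energy.nadph_per_C_CF = 2
energy.atp_per_N_NF = 8
energy.nadph_per_N_NF = 2
energy.atp_maintenance = 1e-05
energy.atp_per_C_RESP = 4.5
rp.vRPmax = 0.00011
rp.kO2RP = 2
cskel.vCSmax = 9e-05
cskel.kCH2O = 0.8
cskel.kCSi = 0.25
exchange.kappa_O2 = 0.0004
exchange.rho_C = 10
alloc.TPSmaxBF = 1e-05
alloc.kFePS_syn = 30
alloc.TBFmaxPS = 0.0037
alloc.kFePS_dec = 30
alloc.TNFmaxBF = 0.006
alloc.kFeBF_syn = 6
alloc.TNFmaxNA = 0.0025
growth.q_N = 0.15873015873015872
growth.c_bio = 0.4
numerics.lim_CH2O = 0.001
numerics.lim_O2 = 0.02
numerics.lim_FeBF = 0.5
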