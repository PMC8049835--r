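# Reference parameter set of the memristive pre-BotC model (published
# values; stimulation terms at their unstimulated defaults).
C: 21.0
sigma: 0.185
gNa: 10.0
gK: 4.0
gL: 2.8
gNaP: 2.8
gtonic_e: 0.3
gCAN: 0.7
VNa: 50.0
VK: -85.0
VL: -65.0
Vsyn_e: 0.0
theta_m: -34.0
theta_mp: -40.0
theta_n: -29.0
theta_h: -48.0
sigma_m: -5.0
sigma_mp: -6.0
sigma_n: -4.0
sigma_h: 6.0
tau_n: 10.0
tau_h: 10000.0
K_CAN: 0.74
n_CAN: 0.97
IP3: 1.2
L_IP3: 0.37
P_IP3: 31000.0
K_I: 1.0
K_a: 0.4
K_d: 0.4
Ca_Tot: 1.25
K_Ca: 0.000025
V_SERCA: 400.0
K_SERCA: 0.2
A: 0.005
Iextz: 0.0
k1: 0.0
k2: 3.0
alpha: 1.0
beta: 0.00006
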