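titration,parameter,wavelength_nm,change_pct
absorption,mua,730,544
absorption,mua,830,286
absorption,musp,730,13
absorption,musp,830,-3
absorption,bfi,NA,19
scattering,musp,730,70
scattering,musp,830,67
scattering,mua,730,-3
scattering,mua,830,-2
scattering,bfi,NA,1
flow,bfi,NA,276
flow,mua,730,-8
flow,mua,830,1
flow,musp,730,0
flow,musp,830,0
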