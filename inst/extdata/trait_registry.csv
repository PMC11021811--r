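name,units,scale
body_mass,g,whole-body
bmc,mg,whole-body
fbg,mg/dL,whole-body
tt_ar,mm2,whole-bone
ct_ar,mm2,whole-bone
ma_ar,mm2,whole-bone
ct_th,mm,whole-bone
pmoi,mm4,whole-bone
tmd,mgHA/cm3,tissue
stiffness,N/mm,whole-bone
ult_force,N,whole-bone
yield_force,N,whole-bone
pyd,mm,whole-bone
work_to_fx,mJ,whole-bone
ult_stress,MPa,tissue
yield_stress,MPa,tissue
modulus,MPa,tissue
porosity,%,tissue
lc_n_density,1/mm3,lacunar
lc_vol_density,%,lacunar
v_vol_density,%,lacunar
lc_vol,um3,lacunar
lc_aspect_ratio,,lacunar
lc_sphericity,,lacunar
lc_max_feret,um,lacunar
lc_vol_sa,um,lacunar
lc_sd_phi,deg,lacunar
mm_v1_proline,,tissue
mm_v2_amide3,,tissue
carb_phos,,tissue
crystallinity,cm,tissue
stiffness_meas,N/mm,whole-bone
yield_force_meas,N,whole-bone
ult_force_meas,N,whole-bone
pyd_meas,mm,whole-bone
work_to_fx_meas,mJ,whole-bone
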