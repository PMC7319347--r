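name	group	served_g	served_kcal	carb_per_g	sugar_per_g	fat_per_g	protein_per_g
cheese_pizza	pizza	790	2009	0.28	0.03	0.10	0.11
vegetable_pizza	pizza	940	2050	0.26	0.03	0.08	0.09
pepperoni_pizza	pizza	825	2199	0.27	0.03	0.12	0.12
hummus	condiment	283	700	0.18	0.01	0.17	0.08
ranch_dressing	condiment	224	880	0.06	0.05	0.42	0.01
vanilla_ice_cream	snack	250	530	0.24	0.21	0.11	0.035
chocolate_chip_cookies	snack	200	970	0.65	0.35	0.24	0.05
fudge_brownies	snack	350	1200	0.52	0.38	0.14	0.04
mms	snack	200	1000	0.71	0.64	0.21	0.04
ruffles_potato_chips	snack	200	1143	0.52	0.02	0.36	0.07
cheetos	snack	250	1339	0.54	0.02	0.34	0.06
baby_carrots	fruit_veg	250	103	0.096	0.047	0.001	0.009
cherry_tomatoes	fruit_veg	300	55	0.039	0.026	0.002	0.009
celery	fruit_veg	200	32	0.030	0.013	0.002	0.007
grapes	fruit_veg	600	414	0.180	0.160	0.002	0.007
water	beverage	591	0	0	0	0	0
regular_coke	beverage	591	240	0.106	0.106	0	0
diet_coke	beverage	591	11	0	0	0	0
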