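name	mz	composition	reduced_end	feature	esnog_cutoff
ox167.0914	167.0914		FALSE	other	0.01
Hex_red	183.0863	Hex1	TRUE	other	0.01
HexNAc_ox	204.0867	HexNAc1	FALSE	other	0.01
HexNAc_hydrate	222.0972		FALSE	other	0.01
HexNAc_red	224.1118	HexNAc1	TRUE	n_glycan	0.03
ox243.0264	243.0264		FALSE	other	0.01
Neu5Ac_H2O	274.0921		FALSE	neu5ac	0.01
SO4HexNAc_ox	284.0435	HexNAc1SO41	FALSE	sulfo_hexnac	0.01
Neu5Gc_H2O	290.087		FALSE	neu5gc	0.01
Neu5Ac_ox	292.1027	Neu5Ac1	FALSE	neu5ac	0.01
Neu5Gc_ox	308.0976	Neu5Gc1	FALSE	neu5gc	0.01
Neu5Ac_red	312.1289	Neu5Ac1	TRUE	other	0.01
ox316.1027	316.1027		FALSE	other	0.01
Neu5Gc_red	328.1238	Neu5Gc1	TRUE	other	0.01
ox332.0976	332.0976		FALSE	other	0.01
AcNeu5Ac_ox	334.1133	Neu5Ac1Ac1	FALSE	oac_neu5ac	0.01
AcNeu5Gc_ox	350.1082	Neu5Gc1Ac1	FALSE	oac_neu5gc	0.01
HexHexNAc_ox	366.1395	Hex1HexNAc1	FALSE	other	0.01
FucHexNAc_red	370.1697	HexNAc1Fuc1	TRUE	other	0.01
HexNAc2_ox	407.1661	HexNAc2	FALSE	other	0.01
SO4HexHexNAc_ox	446.09627	Hex1HexNAc1SO41	FALSE	other	0.01
Neu5AcHexNAc_ox	495.1821	HexNAc1Neu5Ac1	FALSE	sia_hexnac_ac	0.01
Neu5GcHexNAc_ox	511.177	HexNAc1Neu5Gc1	FALSE	sia_hexnac_gc	0.01
FucHexHexNAc_ox	512.1974	Hex1HexNAc1Fuc1	FALSE	fucose_antenna	0.01
Hex2HexNAc_ox	528.1923	Hex2HexNAc1	FALSE	alpha_gal	0.01
HexAHexHexNAc_ox	542.1716	Hex1HexNAc1HexA1	FALSE	hnk1	0.01
FucHexNAc2_ox	553.224	HexNAc2Fuc1	FALSE	lacdinac_fuc	0.01
HexHexNAc2_ox	569.21887	Hex1HexNAc2	FALSE	other	0.01
SO4HexAHexHexNAc_ox	622.1284	Hex1HexNAc1HexA1SO41	FALSE	hnk1_sulfo	0.01
SO4HexHexNAc2_ox	649.17567	Hex1HexNAc2SO41	FALSE	other	0.01
Neu5AcHexHexNAc_ox	657.2349	Hex1HexNAc1Neu5Ac1	FALSE	other	0.01
Fuc2HexHexNAc_ox	658.2553	Hex1HexNAc1Fuc2	FALSE	lewis_y	0.01
Neu5GcHexHexNAc_ox	673.2298	Hex1HexNAc1Neu5Gc1	FALSE	other	0.01
ox698.2615	698.2615		FALSE	other	0.01
AcNeu5AcHexHexNAc_ox	699.2455	Hex1HexNAc1Neu5Ac1Ac1	FALSE	other	0.01
ox714.2564	714.2564		FALSE	other	0.01
AcNeu5GcHexHexNAc_ox	715.2404	Hex1HexNAc1Neu5Gc1Ac1	FALSE	other	0.01
FucHexHexNAc2_ox	715.27677	Hex1HexNAc2Fuc1	FALSE	other	0.01
Hex2HexNAc2_ox	731.27167	Hex2HexNAc2	FALSE	other	0.01
HexHexNAc3_red	792.3234	Hex1HexNAc3	TRUE	bisecting	0.01
Neu5AcFucHexHexNAc_ox	803.2928	Hex1HexNAc1Fuc1Neu5Ac1	FALSE	other	0.01
Neu5GcFucHexHexNAc_ox	819.2877	Hex1HexNAc1Fuc1Neu5Gc1	FALSE	other	0.01
Sda_ox	860.31427	Hex1HexNAc2Neu5Ac1	FALSE	sda	0.01
SdaGc_ox	876.30917	Hex1HexNAc2Neu5Gc1	FALSE	other	0.01
FucHex2HexNAc2_ox	877.32957	Hex2HexNAc2Fuc1	FALSE	other	0.01
diSiaLewisC_Ac_ox	948.3303	Hex1HexNAc1Neu5Ac2	FALSE	disialyl_lewis_c_ac	0.01
diSiaLewisC_Gc_ox	980.3201	Hex1HexNAc1Neu5Gc2	FALSE	disialyl_lewis_c_gc	0.01
Fuc2Hex2HexNAc2_ox	1023.38747	Hex2HexNAc2Fuc2	FALSE	other	0.01
Fuc3Hex2HexNAc2_ox	1169.44537	Hex2HexNAc2Fuc3	FALSE	other	0.01
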