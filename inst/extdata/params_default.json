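{
  "_note": "Default calibrated kinetic parameters for the CSF1R-centered pro-inflammatory GRN model. Functional forms: saturating Hill activation, multiplicative Hill inhibition, first-order degradation; post-translational regulations act on inactive->active protein fluxes (Ka = 0 encodes a rate linear in the source activity, used for the LPS input). Calibrated so that the basal and LPS-activated states, qualitative LPS response classes, perturbation-screen ranking, irreversible bistability and knockdown phenotypes match the documented behaviour of the network; protein/mRNA scale 3000; Irf8 and Csf1 mRNA half-lives 4.1 h and 5.2 h.",
  "protein_mrna_ratio": 3000,
  "kdm_CSF1": 0.133297534723066,
  "kdm_STAT1": 0.0866433975699932,
  "kdm_STAT3": 0.0770163533955495,
  "kdm_IRF8": 0.16906028794145,
  "kdm_PU1": 0.0577622650466621,
  "kdm_NFKB": 0.0990210257942779,
  "kdm_CEBPA": 0.115524530093324,
  "kdm_IL6R": 0.0693147180559945,
  "kdm_TNFR1": 0.0630133800509041,
  "kdm_CSF1R": 0.0533190138892266,
  "kdm_CSF3R": 0.0577622650466621,
  "kdp_STAT1": 0.0693147180559945,
  "ksp_STAT1": 207.944154167984,
  "kin_STAT1": 1,
  "kdp_STAT3": 0.0693147180559945,
  "ksp_STAT3": 207.944154167984,
  "kin_STAT3": 1,
  "kdp_NFKB": 0.0693147180559945,
  "ksp_NFKB": 207.944154167984,
  "kin_NFKB": 1,
  "kdp_CEBPA": 0.115524530093324,
  "ksp_CEBPA": 346.573590279973,
  "kin_CEBPA": 0.5,
  "kdp_CSF1R": 0.0495105128971389,
  "ksp_CSF1R": 148.531538691417,
  "kin_CSF1R": 0.5,
  "ka_r1": 0.05,
  "Ka_r1": 0,
  "n_r1": 1,
  "ka_r9": 0.00425,
  "Ka_r9": 1800,
  "n_r9": 2,
  "ka_r21": 0.007,
  "Ka_r21": 778.209477604178,
  "n_r21": 2,
  "ka_r32": 0.012,
  "Ka_r32": 594.135741252639,
  "n_r32": 2,
  "ka_r31": 0.088,
  "Ka_r31": 20.5079288980773,
  "n_r31": 1,
  "ka_r39": 0.03,
  "Ka_r39": 1440,
  "n_r39": 2,
  "ka_r41": 0.03,
  "Ka_r41": 4320,
  "n_r41": 2,
  "ka_r42": 0.012,
  "Ka_r42": 778.209477604178,
  "n_r42": 2,
  "ka_r13": 0.17,
  "Ka_r13": 1260,
  "n_r13": 1,
  "ka_r34": 0.03825,
  "Ka_r34": 264,
  "n_r34": 1,
  "ka_r19": 0.102,
  "Ka_r19": 1080,
  "n_r19": 1,
  "Ki_r6": 60000,
  "n_r6": 2,
  "Ki_r15": 0.5,
  "n_r15": 2,
  "v_r4": 0.0520692162036631,
  "K_r4": 365.057905897493,
  "n_r4": 2,
  "v_r5": 0.781038243054946,
  "K_r5": 116.758374884151,
  "n_r5": 4,
  "v_r30": 0.222491687587143,
  "K_r30": 87.5432110578855,
  "n_r30": 2,
  "v_r38": 0.0770163533955495,
  "K_r38": 1679.01027164339,
  "n_r38": 2,
  "v_r3": 0.0198042051588556,
  "K_r3": 869.011635746893,
  "n_r3": 2,
  "v_r11": 0.0264056068784741,
  "K_r11": 11456.4392373896,
  "n_r11": 2,
  "v_r12": 0.121025698193006,
  "K_r12": 28.1267675907748,
  "n_r12": 2,
  "v_r25": 0.00779790578129938,
  "K_r25": 11456.4392373896,
  "n_r25": 2,
  "v_r10": 0.161734342130654,
  "K_r10": 632.298840719156,
  "n_r10": 2,
  "v_r24": 0.0361014156541638,
  "K_r24": 31.1594918325988,
  "n_r24": 2,
  "v_r27": 0.0481352208722184,
  "K_r27": 11456.4392373896,
  "n_r27": 2,
  "v_r20": 0.015995704166768,
  "K_r20": 41.0158577961546,
  "n_r20": 1,
  "v_r22": 0.0399892604169199,
  "K_r22": 557.635162272443,
  "n_r22": 2,
  "v_r36": 0.0533190138892266,
  "K_r36": 11456.4392373896,
  "n_r36": 2,
  "v_r14": 0.038261724366909,
  "K_r14": 16.2826358686479,
  "n_r14": 6,
  "v_r16": 0.0635174870913113,
  "K_r16": 25.4416185447623,
  "n_r16": 2,
  "v_r17": 0.0921352560005835,
  "K_r17": 25.4416185447623,
  "n_r17": 2,
  "v_r35": 0.0959742250006078,
  "K_r35": 11456.4392373896,
  "n_r35": 2,
  "v_r28": 0.0269557236884423,
  "K_r28": 11456.4392373896,
  "n_r28": 2,
  "v_r33": 0.0138629436111989,
  "K_r33": 25.4416185447623,
  "n_r33": 2,
  "v_r7": 0.081148938211896,
  "K_r7": 328.126862369237,
  "n_r7": 1,
  "v_r26": 0.13524823035316,
  "K_r26": 8250,
  "n_r26": 4,
  "v_r40": 0.076246189861594,
  "K_r40": 1114.0045148487,
  "n_r40": 4,
  "v_r37": 0.1999463020846,
  "K_r37": 1980.45247084213,
  "n_r37": 4,
  "v_r8": 0.0485203026391962,
  "K_r8": 1640.63431184618,
  "n_r8": 4,
  "v_r23": 0.134297266233489,
  "K_r23": 2970.67870626319,
  "n_r23": 4,
  "v_r18": 0.113424084091627,
  "K_r18": 891.203611878958,
  "n_r18": 4,
  "v_r29": 0.0138629436111989,
  "K_r29": 328.126862369237,
  "n_r29": 4,
  "v_r2": 0.0316867282541689,
  "K_r2": 0.5,
  "n_r2": 2,
  "v0_CSF1": 0.0432101852831855,
  "v0_STAT1": 0.092422858761502,
  "v0_STAT3": 0.107822894753769,
  "v0_IRF8": 0.0713442053620038,
  "v0_PU1": 0.0750909445606607,
  "v0_NFKB": 0.0336671487700545,
  "v0_CEBPA": 0.0121263897884047,
  "v0_IL6R": 0.0137961298528139,
  "v0_TNFR1": 0.033992289894045,
  "v0_CSF1R": 0.0211143295001337,
  "v0_CSF3R": 0.00808333342490926
}
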