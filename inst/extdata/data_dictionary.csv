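table,column,type,description
patients,patient_id,string,Unique patient identifier
patients,diagnosis,string,ICD-10 diagnosis block: F2 (schizophrenic) or F3 (depressive disorders)
patients,gender,string,male or female
patients,age,integer,Age in years at entry
patients,ward,integer,Ward identifier (psychiatrist in charge)
patients,drug_count,integer,Number of simultaneously prescribed psychotropic drugs
patients,igm,number,Serum immunoglobulin M level in g/L (NA when never drawn)
patients,sscl_thought_disorder,number,Lifetime syndrome score: schizophrenic thought disorders (0-24)
patients,sscl_delusions,number,Lifetime syndrome score: delusions (0-20)
patients,sscl_hallucinations,number,Lifetime syndrome score: hallucinations (0-16)
patients,sscl_ego_consciousness,number,Lifetime syndrome score: ego consciousness (0-16)
patients,sscl_incongruent_affect,number,Lifetime syndrome score: incongruent affect (0-12)
patients,sscl_anergia,number,Lifetime syndrome score: anergia (0-16)
patients,sscl_depressive_syndrome,number,Lifetime syndrome score: depressive syndrome (0-32)
patients,sscl_manic_syndrome,number,Lifetime syndrome score: manic syndrome (0-20)
patients,sscl_suicide,number,Lifetime syndrome score: suicide (0-12)
patients,dl,number,Lifetime global depression score DL (12 items; 0-48)
patients,sl,number,Lifetime global schizophrenia score SL (20 items; 0-80)
patients,baseline_hamd17,number,Day-0 HAM-D17 total (0-52); inclusion requires >= 15 for F3
patients,baseline_hamd21,number,Day-0 HAM-D21 total (0-66)
patients,baseline_panss_p,number,Day-0 PANSS positive-scale total (7-49)
patients,baseline_panss_n,number,Day-0 PANSS negative-scale total (7-49)
patients,baseline_panss_g,number,Day-0 PANSS general-scale total (16-112); inclusion requires >= 21 for F2
assessments,patient_id,string,Foreign key into patients
assessments,day,integer,Study day: one of 0 3 7 10 14 21 28 35
assessments,ham_d17,number,HAM-D17 total at this visit
assessments,ham_d21,number,HAM-D21 total at this visit
assessments,panss_p,number,PANSS positive total at this visit
assessments,panss_n,number,PANSS negative total at this visit
assessments,panss_g,number,PANSS general total at this visit
assessments,medis_sleep,number,MEDIS cluster score: sleep (0-18)
assessments,medis_appetite,number,MEDIS cluster score: appetite (0-18)
assessments,medis_sexuality,number,MEDIS cluster score: sexuality (0-18)
assessments,medis_gastrointestinal,number,MEDIS cluster score: gastro-intestinal (0-18)
assessments,medis_autonomic,number,MEDIS cluster score: autonomic (0-18)
assessments,medis_neurological,number,MEDIS cluster score: neurological (0-18)
assessments,medis_cardiovascular,number,MEDIS cluster score: cardiovascular (0-18)
assessments,medis_cardiac_respiratory,number,MEDIS cluster score: cardiac-respiratory (0-18)
assessments,medis_global,number,Global side-effect score S = sum of the 8 clusters (0-144)
truth,patient_id,string,Foreign key into patients (ground truth; never analysis input)
truth,subgroup,logical,TRUE when the patient belongs to the planted IgM-linked subgroup
truth,planted_response,string,Planted response category: responder / partial / non_responder
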