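trial_id,first_author,year,journal,multicenter,double_blinded,registered,itt,outcome_used,n_int,n_ctl,events_int,events_ctl,n_lost_followup,reported_p
T001,Smith,1998,New England Journal of Medicine,yes,yes,no,yes,primary,120,120,10,28,6,0.002
T002,Chen,2005,Journal of Pediatrics,no,no,no,no,secondary,40,40,2,11,3,0.01
T003,Garcia,2012,Pediatrics,yes,unsure,yes,yes,primary,75,75,5,17,0,0.006
T004,Okafor,2015,Neonatology,unsure,no,yes,yes,primary,30,30,1,9,2,0.009
T005,Ivanov,2019,The Lancet,yes,yes,yes,yes,primary,250,250,30,60,20,0.001
T006,Nguyen,2001,JAMA,yes,no,unsure,no,secondary,60,60,4,15,5,
T007,Rossi,1995,Acta Paediatrica,no,no,no,no,primary,25,25,0,7,1,0.004
T008,Khan,2020,Other Journal,no,unsure,no,yes,secondary,180,180,22,48,12,0.003
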