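"specimen_id","species","consignment","outcome"
"SZ001","Tiliqua rugosa",1,"dead_on_arrival"
"SZ002","Tiliqua rugosa",1,"rehomed"
"SZ003","Tiliqua rugosa",1,"rehomed"
"SZ004","Tiliqua rugosa",1,"rehomed"
"SZ005","Tiliqua rugosa",1,"rehomed"
"SZ006","Tiliqua scincoides",2,"rehomed"
"SZ007","Tiliqua scincoides",2,"rehomed"
"SZ008","Tiliqua nigrolutea",3,"rehomed"
"SZ009","Tiliqua nigrolutea",3,"rehomed"
"SZ010","Tiliqua nigrolutea",3,"rehomed"
"SZ011","Tiliqua nigrolutea",3,"rehomed"
"SZ012","Tiliqua rugosa",3,"rehomed"
"SZ013","Tiliqua rugosa",3,"rehomed"
"SZ014","Tiliqua rugosa",3,"rehomed"
"SZ015","Tiliqua rugosa",3,"rehomed"
"SZ016","Tiliqua rugosa",3,"rehomed"
"SZ017","Tiliqua scincoides",4,"rehomed"
"SZ018","Tiliqua scincoides",4,"rehomed"
"SZ019","Tiliqua rugosa",5,"rehomed"
"SZ020","Tiliqua rugosa",5,"rehomed"
"SZ021","Tiliqua rugosa",5,"rehomed"
"SZ022","Tiliqua rugosa",5,"rehomed"
"SZ023","Tiliqua rugosa",5,"rehomed"
"SZ024","Egernia striolata/saxatilis",6,"rehomed"
"SZ025","Egernia striolata/saxatilis",6,"rehomed"
"SZ026","Egernia striolata/saxatilis",6,"rehomed"
"SZ027","Egernia striolata/saxatilis",6,"rehomed"
"SZ028","Egernia striolata/saxatilis",6,"rehomed"
"SZ029","Egernia striolata/saxatilis",6,"rehomed"
"SZ030","Egernia striolata/saxatilis",6,"rehomed"
"SZ031","Egernia striolata/saxatilis",6,"rehomed"
"SZ032","Tiliqua scincoides",6,"rehomed"
"SZ033","Tiliqua scincoides",6,"rehomed"
"SZ034","Tiliqua nigrolutea",7,"rehomed"
"SZ035","Tiliqua nigrolutea",7,"rehomed"
"SZ036","Tiliqua nigrolutea",7,"rehomed"
"SZ037","Tiliqua nigrolutea",7,"rehomed"
"SZ038","Tiliqua rugosa",7,"rehomed"
"SZ039","Tiliqua rugosa",7,"rehomed"
"SZ040","Tiliqua rugosa",7,"rehomed"
"SZ041","Tiliqua rugosa",7,"rehomed"
"SZ042","Tiliqua rugosa",7,"rehomed"
"SZ043","Tiliqua scincoides",8,"rehomed"
"SZ044","Tiliqua scincoides",8,"rehomed"
"SZ045","Tiliqua rugosa",9,"rehomed"
"SZ046","Tiliqua rugosa",9,"rehomed"
"SZ047","Tiliqua rugosa",9,"rehomed"
"SZ048","Tiliqua rugosa",9,"rehomed"
"SZ049","Oedura castelnaui",10,"rehomed"
"SZ050","Oedura castelnaui",10,"rehomed"
"SZ051","Oedura castelnaui",10,"rehomed"
"SZ052","Oedura castelnaui",10,"rehomed"
"SZ053","Oedura castelnaui",10,"rehomed"
"SZ054","Tiliqua scincoides",10,"rehomed"
"SZ055","Tiliqua scincoides",10,"rehomed"
"SZ056","Tiliqua rugosa",11,"rehomed"
"SZ057","Tiliqua rugosa",11,"rehomed"
"SZ058","Tiliqua rugosa",11,"rehomed"
"SZ059","Tiliqua rugosa",11,"rehomed"
"SZ060","Egernia epsisolus",12,"rehomed"
"SZ061","Egernia epsisolus",12,"rehomed"
"SZ062","Egernia epsisolus",12,"rehomed"
"SZ063","Egernia epsisolus",12,"rehomed"
"SZ064","Egernia epsisolus",12,"rehomed"
"SZ065","Egernia epsisolus",12,"rehomed"
"SZ066","Egernia epsisolus",12,"rehomed"
"SZ067","Egernia epsisolus",12,"rehomed"
"SZ068","Egernia epsisolus",12,"rehomed"
"SZ069","Egernia epsisolus",12,"rehomed"
"SZ070","Egernia epsisolus",12,"rehomed"
"SZ071","Egernia epsisolus",12,"rehomed"
"SZ072","Egernia epsisolus",12,"rehomed"
"SZ073","Egernia epsisolus",12,"rehomed"
"SZ074","Egernia epsisolus",12,"rehomed"
"SZ075","Egernia epsisolus",12,"rehomed"
"SZ076","Egernia epsisolus",12,"rehomed"
"SZ077","Egernia epsisolus",12,"rehomed"
"SZ078","Egernia epsisolus",12,"rehomed"
"SZ079","Egernia epsisolus",12,"rehomed"
"SZ080","Egernia epsisolus",12,"rehomed"
"SZ081","Egernia epsisolus",12,"rehomed"
"SZ082","Egernia epsisolus",12,"rehomed"
"SZ083","Egernia epsisolus",12,"rehomed"
"SZ084","Egernia epsisolus",12,"rehomed"
"SZ085","Egernia epsisolus",12,"rehomed"
"SZ086","Egernia epsisolus",12,"rehomed"
"SZ087","Egernia epsisolus",12,"rehomed"
"SZ088","Egernia epsisolus",12,"rehomed"
"SZ089","Egernia epsisolus",12,"euthanized"
"SZ090","Egernia epsisolus",12,"euthanized"
"SZ091","Egernia epsisolus",12,"euthanized"
"SZ092","Egernia epsisolus",12,"euthanized"
"SZ093","Tiliqua rugosa",13,"euthanized"
"SZ094","Tiliqua rugosa",13,"euthanized"
"SZ095","Tiliqua rugosa",13,"euthanized"
"SZ096","Tiliqua rugosa",13,"euthanized"
"SZ097","Euastacus sp.",14,"dead_on_arrival"
"SZ098","Euastacus sp.",14,"dead_on_arrival"
"SZ099","Euastacus sp.",14,"dead_on_arrival"
"SZ100","Euastacus sp.",14,"dead_on_arrival"
"SZ101","Euastacus sp.",14,"dead_on_arrival"
"SZ102","Euastacus sp.",14,"dead_on_arrival"
"SZ103","Euastacus sp.",14,"dead_on_arrival"
"SZ104","Euastacus sp.",14,"dead_on_arrival"
"SZ105","Euastacus sp.",14,"dead_on_arrival"
"SZ106","Euastacus sp.",14,"dead_on_arrival"
"SZ107","Euastacus sp.",14,"dead_on_arrival"
"SZ108","Euastacus sp.",14,"dead_on_arrival"
"SZ109","Euastacus sp.",14,"dead_on_arrival"
"SZ110","Euastacus sp.",14,"dead_on_arrival"
"SZ111","Euastacus sp.",14,"dead_on_arrival"
"SZ112","Tiliqua rugosa",15,"euthanized"
"SZ113","Tiliqua rugosa",15,"euthanized"
"SZ114","Tiliqua rugosa",15,"euthanized"
"SZ115","Tiliqua rugosa",15,"euthanized"
"SZ116","Tiliqua rugosa",16,"euthanized"
"SZ117","Tiliqua rugosa",16,"euthanized"
"SZ118","Tiliqua rugosa",16,"euthanized"
"SZ119","Tiliqua rugosa",16,"euthanized"
"SZ120","Tiliqua multifasciata",17,"euthanized"
"SZ121","Chelodina longicollis",18,"euthanized"
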