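<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="mini" fbc:strict="true">
    <listOfCompartments>
      <compartment id="e" constant="true"/>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_a_e" name="a_e" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_a_c" name="a_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="fb_1" value="-10" constant="true"/>
      <parameter id="fb_2" value="0" constant="true"/>
      <parameter id="fb_3" value="10" constant="true"/>
    </listOfParameters>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_gT1" fbc:label="gT1"/>
      <fbc:geneProduct fbc:id="G_gT2" fbc:label="gT2"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_EX_a" name="EX_a" reversible="true" fast="false" fbc:lowerFluxBound="fb_1" fbc:upperFluxBound="fb_2">
        <listOfReactants>
          <speciesReference species="M_a_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_At" name="At" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <fbc:geneProductAssociation>
          <fbc:or>
            <fbc:geneProductRef fbc:geneProduct="G_gT1"/>
            <fbc:geneProductRef fbc:geneProduct="G_gT2"/>
          </fbc:or>
        </fbc:geneProductAssociation>
        <listOfReactants>
          <speciesReference species="M_a_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_a_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R_DM_a" name="DM_a" reversible="false" fast="false" fbc:lowerFluxBound="fb_2" fbc:upperFluxBound="fb_3">
        <listOfReactants>
          <speciesReference species="M_a_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_DM_a" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
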